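#' Core scenario set
#'
#' The six core perturbation scenarios entering the total-risk sum and the
#' median susceptibility rank: juvenile-survival reduction, fertility
#' reduction, all-ages survival reduction, individual offtake, catastrophe
#' frequency, catastrophe magnitude. The sub-scenarios (juvenile-only
#' offtake, egg harvest) are reported separately.
#'
#' @return character vector of scenario kinds.
#' @export
core_scenarios <- function() {
  c("juvenile_survival", "fertility", "all_survival", "offtake",
    "cat_frequency", "cat_magnitude")
}

#' Build the intensity grid for a perturbation scenario
#'
#' Proportional scenarios (`juvenile_survival`, `fertility`, `all_survival`)
#' sweep 0 to 1 in steps of `grid_step` (default 0.05, i.e. 21 settings).
#' Unbounded scenarios sweep up to the species-specific saturation point
#' where quasi-extinction is certain: `offtake` and `offtake_juvenile` sweep
#' annual removals over 0 and `n_points` log-spaced values up to `n_stop`;
#' `egg_harvest` likewise up to `n_stop` eggs removed per female-year;
#' `cat_frequency` sweeps frequency multipliers over `n_points` log-spaced
#' values from 1 to `m_max`. `cat_magnitude` sweeps severity from 0.5 to 1
#' (step `grid_step`), each iteration drawing its frequency multiplier
#' uniformly from \[1, `m_max`\]. Saturation points `n_stop` / `m_max` are
#' found with [find_saturation_intensity()] when not supplied.
#'
#' @param kind a perturbation kind (see [perturbation()]).
#' @param params species, required when a saturation point must be searched.
#' @param config [sim_config()] used for the saturation search.
#' @param grid_step grid increment for proportional (and severity) sweeps.
#' @param n_points number of nonzero grid points for unbounded sweeps.
#' @param m_max catastrophe-frequency multiplier at which Pr(E_q) = 1.
#' @param n_stop removal (or egg-harvest) intensity at which Pr(E_q) = 1.
#' @param egg_fraction fraction of total fecundity contributed by egg
#'   production (egg-harvest scenario), see [egg_harvest_fertility()].
#' @return list of [perturbation()] settings with increasing intensity.
#' @export
make_scenario <- function(kind, params = NULL, config = NULL,
                          grid_step = 0.05, n_points = 20,
                          m_max = NULL, n_stop = NULL, egg_fraction = NULL) {
  proportional <- c("juvenile_survival", "fertility", "all_survival")
  if (kind %in% proportional) {
    grid <- seq(0, 1, by = grid_step)
    return(lapply(grid, function(i) perturbation(kind, i)))
  }
  if (kind %in% c("offtake", "offtake_juvenile", "egg_harvest")) {
    if (is.null(n_stop)) {
      if (is.null(params) || is.null(config))
        stop("make_scenario('", kind,
             "') needs n_stop or (params, config) to search for it")
      n_stop <- find_saturation_intensity(params, config, kind,
                                          egg_fraction = egg_fraction)
    }
    grid <- c(0, logspace_grid(n_stop, n_points))
    extra <- if (kind == "egg_harvest") list(egg_fraction = egg_fraction)
             else list()
    return(lapply(grid, function(i) perturbation(kind, i, extra = extra)))
  }
  if (kind == "cat_frequency") {
    if (is.null(m_max)) {
      if (is.null(params) || is.null(config))
        stop("make_scenario('cat_frequency') needs m_max or (params, config)")
      m_max <- find_saturation_intensity(params, config, "cat_frequency")
    }
    grid <- exp(seq(log(1), log(m_max), length.out = n_points))
    return(lapply(grid, function(i) perturbation("cat_frequency", i)))
  }
  if (kind == "cat_magnitude") {
    if (is.null(m_max))
      stop("make_scenario('cat_magnitude') needs m_max (from the ",
           "cat_frequency saturation search)")
    grid <- seq(0.5, 1, by = grid_step)
    return(lapply(grid, function(i)
      perturbation("cat_magnitude", i, extra = list(m_max = m_max))))
  }
  stop("unknown scenario kind: ", kind)
}

# log-spaced grid from ~x_max/2^(n-1) up to x_max (doubling-style ladder)
logspace_grid <- function(x_max, n_points) {
  stopifnot(x_max > 0, n_points >= 2)
  exp(seq(log(x_max / 2^(n_points / 3)), log(x_max), length.out = n_points))
}

#' Search the perturbation intensity at which quasi-extinction is certain
#'
#' Doubling search followed by bisection on the smallest intensity at which
#' every Monte Carlo run falls below the quasi-extinction threshold
#' (Pr(E_q) = 1). Used to set the upper end of unbounded sweep grids
#' (offtake removals, egg harvest, catastrophe-frequency multipliers).
#'
#' @param params species.
#' @param config [sim_config()]; the search typically uses fewer iterations
#'   than the sweep itself.
#' @param kind `"offtake"`, `"offtake_juvenile"`, `"egg_harvest"` or
#'   `"cat_frequency"`.
#' @param egg_fraction required for `"egg_harvest"`.
#' @param rel_tol relative bisection tolerance on the intensity.
#' @param max_doublings cap on the doubling phase.
#' @return the saturation intensity (same units as the perturbation).
#' @export
find_saturation_intensity <- function(params, config, kind,
                                      egg_fraction = NULL, rel_tol = 0.1,
                                      max_doublings = 40) {
  stopifnot(kind %in% c("offtake", "offtake_juvenile", "egg_harvest",
                        "cat_frequency"))
  extra <- if (kind == "egg_harvest") {
    if (is.null(egg_fraction)) stop("egg_harvest search needs egg_fraction")
    list(egg_fraction = egg_fraction)
  } else list()
  all_extinct <- function(i) {
    pr <- project(params, config, perturbation(kind, i, extra = extra))$pr_eq
    pr >= 1
  }
  lo <- if (kind == "cat_frequency") 1 else 0
  hi <- if (kind == "cat_frequency") 2 else
    max(1, params$density * config$area_km2 / 100)
  found <- FALSE
  for (d in seq_len(max_doublings)) {
    if (all_extinct(hi)) { found <- TRUE; break }
    lo <- hi
    hi <- hi * 2
  }
  if (!found) {
    warning("saturation search for '", kind, "' on species '", params$name,
            "' did not reach Pr(E_q) = 1 by intensity ", hi,
            "; using that bound")
    return(hi)
  }
  while ((hi - lo) > rel_tol * hi) {
    mid <- if (lo <= 0) hi / 2 else sqrt(lo * hi)  # geometric midpoint
    if (all_extinct(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Egg-harvest arithmetic for bird fertility
#'
#' The harvestable egg pool is the egg-production component of total
#' fecundity: `egg_fraction` is the proportion of total fecundity
#' contributed by individual egg production (for the emu this is nest
#' success 0.406 x hatching probability 0.419 = 0.17, see
#' [dromaius_egg_fraction()]). Removing `eggs_removed` eggs per female-year
#' (half of which would have been daughters at a 1:1 sex ratio) reduces
#' realized fertility by `min(eggs_removed / 2, daughter-egg pool)`; the
#' result is never negative.
#'
#' @param total_fertility total annual fecundity (per female).
#' @param eggs_removed mean eggs removed per female per year (>= 0).
#' @param egg_fraction proportion of total fecundity from egg production,
#'   in \[0, 1\].
#' @return realized fertility after harvest.
#' @examples
#' egg_harvest_fertility(3.87, eggs_removed = 2, egg_fraction = 1)
#' @export
egg_harvest_fertility <- function(total_fertility, eggs_removed, egg_fraction) {
  stopifnot(total_fertility >= 0, eggs_removed >= 0,
            egg_fraction >= 0, egg_fraction <= 1)
  daughter_pool <- egg_fraction * total_fertility / 2
  max(0, total_fertility - min(eggs_removed / 2, daughter_pool))
}

#' Emu egg-production fraction of total fecundity
#'
#' Nest success times hatching probability for \emph{Dromaius}: the
#' proportion of total fecundity contributed by individual egg production,
#' used to transfer an egg-harvest scenario onto other bird species.
#'
#' @param nest_success probability a nest succeeds (default 0.406).
#' @param hatching_prob probability an egg hatches (default 0.419).
#' @return the egg-production fraction (default arguments give 0.17).
#' @export
dromaius_egg_fraction <- function(nest_success = 0.406, hatching_prob = 0.419) {
  stopifnot(nest_success >= 0, nest_success <= 1,
            hatching_prob >= 0, hatching_prob <= 1)
  nest_success * hatching_prob
}

#' Daughter-egg production from total egg production
#'
#' Halves an annual per-female egg production under a 1:1 sex ratio, e.g.
#' 7.74 eggs per year yields 3.87 daughter eggs.
#'
#' @param eggs_per_year per-individual annual egg production.
#' @return daughter eggs per female per year.
#' @export
daughter_eggs <- function(eggs_per_year) {
  stopifnot(eggs_per_year >= 0)
  eggs_per_year / 2
}

#' Sweep a scenario over its intensity grid
#'
#' Projects the species once per grid setting (common random numbers: the
#' configured seed is re-applied at every setting so consecutive grid points
#' are positively coupled) and records the proportion of runs ending below
#' the quasi-extinction threshold. The result carries both the normalized
#' trapezoidal integral (intensity axis rescaled to \[0, 1\], the default
#' cross-scenario risk measure) and the raw-axis integral.
#'
#' @param params species.
#' @param config [sim_config()].
#' @param scenario_settings list of [perturbation()] settings from
#'   [make_scenario()].
#' @return an object of class `qe_curve` with `intensities`, `pr_eq`,
#'   `integral` (normalized axis), `integral_raw`, `kind` and `species`.
#' @export
sweep_scenario <- function(params, config, scenario_settings) {
  stopifnot(length(scenario_settings) >= 2)
  kind <- scenario_settings[[1]]$kind
  intens <- vapply(scenario_settings, function(s) s$intensity, numeric(1))
  if (is.unsorted(intens)) stop("scenario grid must be increasing")
  pr <- vapply(scenario_settings, function(s) {
    project(params, config, s)$pr_eq
  }, numeric(1))
  curve <- structure(list(
    species = params$name, kind = kind,
    intensities = intens, pr_eq = pr,
    integral = NA_real_, integral_raw = NA_real_
  ), class = "qe_curve")
  curve$integral <- integrate_curve(curve)
  curve$integral_raw <- integrate_curve(curve, normalize = FALSE)
  curve
}

#' @export
print.qe_curve <- function(x, ...) {
  cat(sprintf("<qe_curve> %s | %s | %d grid points | integral %.4f\n",
              x$species, x$kind, length(x$intensities), x$integral))
  invisible(x)
}

#' Area under a quasi-extinction curve
#'
#' Trapezoidal integral of Pr(E_q) against perturbation intensity. With
#' `normalize = TRUE` (default) the intensity axis is first rescaled to
#' \[0, 1\] (min-max), so integrals are unit-free and comparable across
#' scenarios; the result then lies in \[0, 1\].
#'
#' @param curve a `qe_curve`, or a list with `intensities` and `pr_eq`.
#' @param normalize rescale the intensity axis to \[0, 1\] first.
#' @return the integral (scalar).
#' @export
integrate_curve <- function(curve, normalize = TRUE) {
  x <- curve$intensities; y <- curve$pr_eq
  if (length(x) < 2) stop("need at least 2 grid points to integrate")
  if (length(x) != length(y)) stop("intensities and pr_eq differ in length")
  if (normalize) {
    rng <- diff(range(x))
    if (rng == 0) stop("degenerate grid: all intensities equal")
    x <- (x - min(x)) / rng
  }
  sum(diff(x) * (head_vec(y) + tail_vec(y)) / 2)
}

head_vec <- function(v) v[-length(v)]
tail_vec <- function(v) v[-1]
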