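#' Simulation configuration
#'
#' Collects every knob of the stochastic projection: Monte Carlo size, study
#' area, quasi-extinction threshold, horizon and burn-in (both in units of
#' generation length, converted to years with round-half-up), and the
#' baseline catastrophe regime.
#'
#' Defaults follow the analysis design: 10,000 iterations, A = 250,000 km^2,
#' quasi-extinction threshold E_q = 50 females (100 total individuals at a
#' 1:1 sex ratio), horizon 40 x round(G) years with round(G) years of
#' burn-in, catastrophes of ~50% mortality occurring with baseline
#' probability 0.14 per generation.
#'
#' @param iterations Monte Carlo iterations per grid point.
#' @param area_km2 study-zone area A (km^2).
#' @param eq_threshold_females quasi-extinction threshold (females).
#' @param horizon_generations projection horizon in generations.
#' @param burnin_generations burn-in discarded from trajectory records, in
#'   generations.
#' @param seed integer RNG seed, or `NULL` to leave the RNG stream alone.
#' @param cat_prob_per_generation baseline catastrophe probability per
#'   generation.
#' @param cat_severity baseline proportional die-off of a catastrophe.
#' @param census matrix census convention, see [build_leslie()].
#' @param g_method generation-length definition, see [generation_length()].
#' @param stochastic logical; `FALSE` gives the deterministic matrix-power
#'   limit (no demographic stochasticity, no catastrophe draws).
#' @param first_passage logical; if `TRUE`, quasi-extinction means the
#'   post-burn-in minimum (not the final total) fell below the threshold.
#' @param premultiply_n0 logical, see [initial_population()].
#' @param feedback_theta compensatory-feedback shape exponent (1 =
#'   compensatory, >1 increasingly abrupt near K).
#' @param store_trajectories logical or `NULL` (auto: store when
#'   `iterations <= 1000`).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(iterations = 10000, area_km2 = 250000,
                       eq_threshold_females = 50,
                       horizon_generations = 40, burnin_generations = 1,
                       seed = NULL, cat_prob_per_generation = 0.14,
                       cat_severity = 0.5,
                       census = c("pre", "post-literal"),
                       g_method = c("abar", "logR0"),
                       stochastic = TRUE, first_passage = FALSE,
                       premultiply_n0 = TRUE, feedback_theta = 1,
                       store_trajectories = NULL) {
  census <- match.arg(census)
  g_method <- match.arg(g_method)
  stopifnot(iterations >= 1, area_km2 > 0, eq_threshold_females >= 1,
            horizon_generations >= 1, burnin_generations >= 0,
            cat_prob_per_generation >= 0, cat_prob_per_generation <= 1,
            cat_severity >= 0, cat_severity <= 1, feedback_theta > 0)
  structure(list(
    iterations = as.integer(iterations), area_km2 = area_km2,
    eq_threshold_females = eq_threshold_females,
    horizon_generations = as.integer(horizon_generations),
    burnin_generations = as.integer(burnin_generations),
    seed = seed, cat_prob_per_generation = cat_prob_per_generation,
    cat_severity = cat_severity, census = census, g_method = g_method,
    stochastic = isTRUE(stochastic), first_passage = isTRUE(first_passage),
    premultiply_n0 = isTRUE(premultiply_n0),
    feedback_theta = feedback_theta,
    store_trajectories = store_trajectories
  ), class = "sim_config")
}

#' Compensatory density-feedback survival multiplier
#'
#' Survival at total abundance N is scaled by
#' \deqn{s(N) = 1 / (1 + c\,(N/K)^\theta),}
#' which is 1 in the empty-population limit, strictly decreasing in N, and
#' calibrated (via [calibrate_feedback()]) so that the deterministic
#' population is stationary at N = K. \eqn{\theta = 1} gives plain
#' compensation; larger values push the response toward the ceiling.
#'
#' @param total_n total abundance N (>= 0).
#' @param K carrying abundance (> 0), typically D x A.
#' @param c calibrated feedback strength (>= 0).
#' @param theta shape exponent (> 0).
#' @return multiplier in (0, 1].
#' @export
density_feedback <- function(total_n, K, c, theta = 1) {
  if (!is.numeric(K) || any(K <= 0)) stop("K must be > 0")
  stopifnot(total_n >= 0, c >= 0, theta > 0)
  1 / (1 + c * (total_n / K)^theta)
}

#' Calibrate the density-feedback strength for a species
#'
#' Finds the survival multiplier \eqn{s^*} at which the feedback-scaled
#' projection matrix has dominant eigenvalue exactly 1 (root-finding on the
#' eigenvalue), then returns \eqn{c = 1/s^* - 1} so that
#' [density_feedback()] yields \eqn{s^*} at N = K. Scaling multiplies every
#' survival probability; under the pre-breeding census the first matrix row
#' contains a survival factor and is scaled too.
#'
#' A model with \eqn{\lambda \le 1} needs no regulation: `c = 0` is returned
#' with a warning (purely compensatory feedback cannot raise growth).
#'
#' @param model a [build_leslie()] model.
#' @return feedback strength `c >= 0`.
#' @export
calibrate_feedback <- function(model) {
  stopifnot(inherits(model, "leslie_model"))
  if (model$lambda <= 1 + 1e-12) {
    if (model$lambda < 1 - 1e-9)
      warning("species '", model$params$name, "' has lambda = ",
              signif(model$lambda, 6),
              " < 1; compensatory feedback cannot stabilize it (c = 0)")
    return(0)
  }
  f <- function(s) scaled_lambda(model, s) - 1
  s_star <- uniroot(f, interval = c(1e-8, 1), tol = 1e-12)$root
  1 / s_star - 1
}

# dominant eigenvalue of the model matrix with all survival entries scaled
# by s (first row included under the pre-breeding census)
scaled_lambda <- function(model, s) {
  M <- model$matrix
  k <- nrow(M)
  Ms <- M * 0
  Ms[1, ] <- if (model$census == "pre") M[1, ] * s else M[1, ]
  if (k > 1L) Ms[cbind(2:k, 1:(k - 1L))] <- M[cbind(2:k, 1:(k - 1L))] * s
  Ms[k, k] <- Ms[k, k] + M[k, k] * s
  dominant_eigen_value(Ms)
}

dominant_eigen_value <- function(M) {
  vals <- eigen(M, only.values = TRUE)$values
  max(Re(vals[Mod(vals) > max(Mod(vals)) * (1 - 1e-9)]))
}

#' One stochastic time step (reference implementation)
#'
#' Advances an age-structured vector one year under the package's sampling
#' law: survivors of age class x are Binomial(round(n_x), S_x s) where s is
#' the feedback multiplier, and age-0 recruits are Poisson with mean equal to
#' the realized (feedback-adjusted) first-row contribution, so the
#' expectation of the step equals the feedback-adjusted deterministic
#' product. This R-level function defines the law; [project()] runs the same
#' law in compiled code.
#'
#' @param n non-negative abundance vector, length \eqn{\omega + 1}.
#' @param model a [build_leslie()] model.
#' @param feedback_multiplier survival multiplier in (0, 1].
#' @return next-year abundance vector.
#' @export
step_stochastic <- function(n, model, feedback_multiplier = 1) {
  stopifnot(inherits(model, "leslie_model"))
  if (any(n < 0)) stop("negative abundances in n")
  s <- feedback_multiplier
  stopifnot(s > 0, s <= 1)
  S <- model$params$survival
  Fv <- model$matrix[1, ]
  if (model$census == "pre") Fv <- Fv * s
  k <- length(n)
  out <- numeric(k)
  mean_rec <- sum(Fv * n)
  out[1] <- if (mean_rec > 0) rpois(1, mean_rec) else 0
  sizes <- round_half_up(n)
  if (k > 1L)
    out[2:k] <- rbinom(k - 1L, sizes[1:(k - 1L)], pmin(1, S[1:(k - 1L)] * s))
  if (model$params$terminal_self_loop)
    out[k] <- out[k] + rbinom(1, sizes[k], min(1, S[k] * s))
  out
}

#' Apply a catastrophic die-off
#'
#' With probability `prob_per_year` every age class is thinned binomially by
#' the factor `1 - severity`; otherwise the vector is returned unchanged.
#' The annual probability is the per-generation catastrophe probability
#' divided by round(G).
#'
#' @param n non-negative abundance vector.
#' @param prob_per_year annual event probability in \[0, 1\].
#' @param severity proportional die-off in \[0, 1\] (0.5 = halve the
#'   population).
#' @return thinned (or unchanged) abundance vector.
#' @export
apply_catastrophe <- function(n, prob_per_year, severity) {
  stopifnot(prob_per_year >= 0, prob_per_year <= 1,
            severity >= 0, severity <= 1, all(n >= 0))
  if (runif(1) < prob_per_year)
    rbinom(length(n), round_half_up(n), 1 - severity)
  else n
}

#' Project a species stochastically under a perturbation
#'
#' Runs `config$iterations` independent annual projections of the species,
#' each started from \eqn{n_0 = A D \mathbf{Mw}}, for
#' `40 x round(G)` years (round-half-up), with compensatory density feedback
#' calibrated to K = D x A, baseline catastrophes, demographic stochasticity
#' and the requested perturbation. The first `round(G)` years are discarded
#' as burn-in from trajectory records; quasi-extinction is scored on the
#' final total (< E_q females), or on the post-burn-in minimum when
#' `config$first_passage` is `TRUE`.
#'
#' @param params a [species_params()] object.
#' @param config a [sim_config()].
#' @param perturbation a [perturbation()] setting (default: none).
#' @return an object of class `pva_projection` with `pr_eq` (proportion of
#'   runs quasi-extinct), `quasi_extinct`, `final_total`,
#'   `min_after_burnin`, the per-year `totals` matrix when trajectories are
#'   stored, and bookkeeping (`n0`, `K`, `feedback_c`, `steps`, `burnin`,
#'   `G`).
#' @export
project <- function(params, config = sim_config(), perturbation = perturbation_none()) {
  stopifnot(inherits(params, "species_params"), inherits(config, "sim_config"),
            inherits(perturbation, "pva_perturbation"))
  eff <- apply_static_perturbation(params, perturbation)
  base_model <- build_leslie(params, census = config$census,
                             g_method = config$g_method)
  # a perturbation can legitimately zero the whole matrix (e.g. all-ages
  # survival reduced by 100%): the population dies in one step
  zero_matrix <- all(eff$survival == 0) &&
    (config$census == "pre" || all(eff$fertility == 0))
  model <- if (zero_matrix) base_model else
    build_leslie(eff, census = config$census, g_method = config$g_method)
  G <- base_model$G
  if (!is.finite(G)) stop("species '", params$name, "' has undefined G")
  Gr <- max(1L, round_half_up(G))
  steps <- config$horizon_generations * Gr
  burnin <- config$burnin_generations * Gr

  K <- params$density * config$area_km2
  n0 <- initial_population(params, base_model, area_km2 = config$area_km2,
                           premultiply = config$premultiply_n0)
  if (all(n0 == 0))
    stop("species '", params$name, "' has an all-zero initial population")
  # feedback calibrated on the UNPERTURBED model: regulation is a property of
  # the species, the perturbation then acts against it
  fb_c <- calibrate_feedback(base_model)

  cat_prob <- cat_prob_vector(perturbation, config, Gr)
  severity <- if (perturbation$kind == "cat_magnitude")
    perturbation$intensity else config$cat_severity
  offtake <- offtake_vector(perturbation, base_model)

  store <- config$store_trajectories
  if (is.null(store)) store <- config$iterations <= 1000

  if (!is.null(config$seed)) set.seed(config$seed)
  fert_row <- if (zero_matrix) numeric(length(eff$survival)) else model$matrix[1, ]
  res <- sim_engine(
    surv = eff$survival, fert_row = fert_row,
    self_loop = eff$terminal_self_loop, n0 = n0,
    steps = as.integer(steps), iterations = config$iterations,
    K = K, fb_c = fb_c, fb_theta = config$feedback_theta,
    cat_prob = cat_prob,
    cat_severity = if (config$stochastic) severity else 0,
    offtake = offtake, eq_threshold = config$eq_threshold_females,
    stochastic = config$stochastic, scale_fert_row = config$census == "pre",
    store_totals = isTRUE(store), burnin = as.integer(burnin))

  qe <- if (config$first_passage)
    res$min_after_burnin < config$eq_threshold_females else res$quasi_extinct
  structure(list(
    species = params$name, pr_eq = mean(qe), quasi_extinct = qe,
    final_total = res$final_total, min_after_burnin = res$min_after_burnin,
    totals = res$totals, n0 = n0, K = K, feedback_c = fb_c,
    steps = steps, burnin = burnin, G = G,
    perturbation = perturbation
  ), class = "pva_projection")
}

#' @export
print.pva_projection <- function(x, ...) {
  cat(sprintf("<pva_projection> %s | %s(%.4g) | %d iterations, %d yr\n",
              x$species, x$perturbation$kind, x$perturbation$intensity,
              length(x$quasi_extinct), x$steps))
  cat(sprintf("  Pr(E_q) = %.4f | K = %.4g | feedback c = %.4g | G = %.2f\n",
              x$pr_eq, x$K, x$feedback_c, x$G))
  invisible(x)
}

# annual catastrophe probability (length 1, or per-iteration for the
# magnitude scenario, whose runs each draw a frequency multiplier)
cat_prob_vector <- function(perturbation, config, Gr) {
  base <- config$cat_prob_per_generation / Gr
  if (!config$stochastic) return(0)
  switch(perturbation$kind,
    cat_frequency = min(1, base * perturbation$intensity),
    cat_magnitude = {
      m_max <- perturbation$extra$m_max
      if (is.null(m_max))
        stop("cat_magnitude perturbation needs extra$m_max (see make_scenario)")
      mult <- runif(config$iterations, 1, m_max)
      pmin(1, base * mult)
    },
    base)
}

# annual per-age-class removal counts (females/yr), apportioned by the
# stable age distribution (restricted to juvenile classes for offtake_juvenile)
offtake_vector <- function(perturbation, model) {
  k <- nrow(model$matrix)
  if (!perturbation$kind %in% c("offtake", "offtake_juvenile"))
    return(numeric(k))
  w <- model$w
  if (perturbation$kind == "offtake_juvenile") {
    keep <- seq_len(model$params$alpha)  # ages 0..alpha-1
    wj <- numeric(k)
    wj[keep] <- w[keep]
    if (sum(wj) == 0) stop("no juvenile mass in stable age distribution")
    w <- wj / sum(wj)
  }
  perturbation$intensity * w
}

#' Perturbation settings
#'
#' A perturbation names the vital rate or process being degraded and its
#' intensity. Kinds and intensity units:
#' \describe{
#'   \item{none}{no perturbation (intensity ignored).}
#'   \item{juvenile_survival}{proportional reduction of \eqn{S_x} for
#'     x < alpha, intensity in \[0,1\].}
#'   \item{fertility}{proportional reduction of every \eqn{m_x}, \[0,1\].}
#'   \item{all_survival}{proportional reduction of every \eqn{S_x}, \[0,1\].}
#'   \item{offtake}{females removed per year, apportioned across ages by the
#'     stable age distribution.}
#'   \item{offtake_juvenile}{as `offtake`, juvenile ages only.}
#'   \item{egg_harvest}{mean eggs removed per female per year (bird
#'     species); see [egg_harvest_fertility()].}
#'   \item{cat_frequency}{multiplier (>= 1) on the baseline per-generation
#'     catastrophe probability.}
#'   \item{cat_magnitude}{catastrophe severity in \[0.5, 1\]; each iteration
#'     draws a frequency multiplier uniformly from \[1, m_max\]
#'     (`extra$m_max`).}
#' }
#'
#' @param kind perturbation kind, see Details.
#' @param intensity non-negative intensity in the kind's units.
#' @param extra list of kind-specific extras (e.g. `m_max`, `egg_fraction`).
#' @return an object of class `pva_perturbation`.
#' @export
perturbation <- function(kind = c("none", "juvenile_survival", "fertility",
                                  "all_survival", "offtake",
                                  "offtake_juvenile", "egg_harvest",
                                  "cat_frequency", "cat_magnitude"),
                         intensity = 0, extra = list()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(intensity), length(intensity) == 1L, intensity >= 0)
  if (kind %in% c("juvenile_survival", "fertility", "all_survival") &&
      intensity > 1)
    stop("proportional intensity must lie in [0, 1]")
  if (kind == "cat_magnitude" && (intensity < 0 || intensity > 1))
    stop("catastrophe severity must lie in [0, 1]")
  structure(list(kind = kind, intensity = intensity, extra = extra),
            class = "pva_perturbation")
}

#' @rdname perturbation
#' @export
perturbation_none <- function() perturbation("none", 0)

# returns a species_params with static (rate-level) perturbations applied;
# process-level kinds (offtake, catastrophes) leave the rates untouched
apply_static_perturbation <- function(params, pert) {
  sp <- params
  i <- pert$intensity
  switch(pert$kind,
    juvenile_survival = {
      idx <- seq_len(sp$alpha)  # ages 0..alpha-1
      sp$survival[idx] <- sp$survival[idx] * (1 - i)
    },
    fertility = {
      sp$fertility <- sp$fertility * (1 - i)
    },
    all_survival = {
      sp$survival <- sp$survival * (1 - i)
    },
    egg_harvest = {
      egg_fraction <- pert$extra$egg_fraction
      if (is.null(egg_fraction))
        stop("egg_harvest perturbation needs extra$egg_fraction")
      total_f <- sum(sp$fertility)
      if (total_f > 0) {
        realized <- egg_harvest_fertility(total_f, i, egg_fraction)
        sp$fertility <- sp$fertility * (realized / total_f)
      }
    },
    NULL)
  # reconstruct through the validating constructor
  species_params(sp$name, sp$status, sp$group, sp$mass_kg, sp$alpha, sp$omega,
                 sp$survival, sp$fertility, sp$density, sp$terminal_self_loop)
}
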