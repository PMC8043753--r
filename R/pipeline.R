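#' Read a simulation configuration file
#'
#' JSON (default) or YAML (if the yaml package is installed) mapping of
#' [sim_config()] argument names to values; unspecified fields keep their
#' defaults.
#'
#' @param path config file; extension `.yml`/`.yaml` selects the YAML
#'   reader.
#' @return a [sim_config()].
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Write quasi-extinction curves as a tidy CSV
#'
#' @param curves list of `qe_curve` objects.
#' @param path output CSV (`species`, `scenario`, `intensity`, `pr_eq`).
#' @return invisibly `path`.
#' @export
write_curves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(species = cv$species, scenario = cv$kind,
               intensity = cv$intensities, pr_eq = cv$pr_eq,
               stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full susceptibility pipeline
#'
#' For every species x scenario, builds the intensity grid, sweeps the
#' quasi-extinction curve, then summarises integrals into ranks, total risk
#' and median rank, regresses risk on log10 mass and log10 generation
#' length, and (when windows are supplied) tests concordance with the
#' extinction chronology. Writes tidy CSVs, a JSON regression report and a
#' JSON run manifest into `out_dir`; partial per-species failures are
#' recorded in the manifest and do not abort the run.
#'
#' @param species named list of [species_params()] (e.g. from
#'   [read_species_table()] or [generate_species_table()]).
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param scenarios scenario kinds to sweep (default: the six core ones).
#' @param windows optional extinction-window table for the chronology
#'   analysis.
#' @param grid_step,n_points grid controls, see [make_scenario()].
#' @param search_iterations Monte Carlo size for saturation searches
#'   (smaller than the sweep size for speed).
#' @param egg_fraction egg-production fraction used if `"egg_harvest"` is
#'   among `scenarios` (applied to bird species only).
#' @return invisibly, a list with `curves`, `summary` (risk table),
#'   `regressions`, `chronology` and `manifest`.
#' @export
run_pipeline <- function(species, config = sim_config(), out_dir = ".",
                         scenarios = core_scenarios(), windows = NULL,
                         grid_step = 0.05, n_points = 20,
                         search_iterations = max(100, config$iterations %/% 10),
                         egg_fraction = dromaius_egg_fraction()) {
  stopifnot(length(species) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  search_cfg <- config
  search_cfg$iterations <- as.integer(search_iterations)

  curves <- list()
  failures <- list()
  m_max_cache <- list()
  for (sp in species) {
    for (kind in scenarios) {
      if (kind == "egg_harvest" && sp$group != "bird") next
      key <- paste(sp$name, kind, sep = "|")
      res <- tryCatch({
        settings <- build_settings(kind, sp, config, search_cfg, grid_step,
                                   n_points, egg_fraction, m_max_cache)
        if (kind == "cat_frequency")
          m_max_cache[[sp$name]] <- max(vapply(settings,
            function(s) s$intensity, numeric(1)))
        sweep_scenario(sp, config, settings)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[key]] <- conditionMessage(res)
      } else {
        curves[[key]] <- res
      }
    }
  }
  if (!length(curves)) stop("every species x scenario sweep failed")
  write_curves(curves, file.path(out_dir, "qe_curves.csv"))

  integral_df <- curves_to_integrals(curves)
  summary_df <- NULL
  if (all(core_scenarios() %in% names(integral_df))) {
    summary_df <- risk_summary(integral_df)
    write.csv(summary_df, file.path(out_dir, "risk_summary.csv"),
              row.names = FALSE)
  }

  regressions <- NULL
  chronology <- NULL
  if (!is.null(summary_df)) {
    info <- species_info(species)
    df <- merge(summary_df, info, by = "species")
    regressions <- list()
    for (sc in intersect(scenarios, names(integral_df))) {
      regressions[[sc]] <- list(
        vs_log10_mass = strip_fit(fit_allometry(log10(df$mass_kg), df[[sc]])),
        vs_log10_G = strip_fit(fit_allometry(log10(df$G), df[[sc]])))
    }
    regressions$median_rank_vs_log10_G <-
      strip_fit(fit_allometry(log10(df$G), df$median_rank))
    jsonlite::write_json(regressions,
                         file.path(out_dir, "regressions.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(windows)) {
      risk_vec <- setNames(df$median_rank, df$species)
      chronology <- chronology_concordance(windows, risk_vec, n_perm = 0)
      chronology$fit_midpoint <- strip_fit(chronology$fit_midpoint)
      chronology$fit_earliest <- strip_fit(chronology$fit_earliest)
      chronology$fit_latest <- strip_fit(chronology$fit_latest)
      jsonlite::write_json(chronology,
                           file.path(out_dir, "chronology.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("paleopva")),
    seed = config$seed,
    config = unclass(config),
    n_species = length(species),
    scenarios = scenarios,
    outputs = list.files(out_dir),
    failures = failures,
    wallclock_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(curves = curves, summary = summary_df,
                 regressions = regressions, chronology = chronology,
                 manifest = manifest))
}

build_settings <- function(kind, sp, config, search_cfg, grid_step, n_points,
                           egg_fraction, m_max_cache) {
  if (kind == "cat_magnitude") {
    m_max <- m_max_cache[[sp$name]]
    if (is.null(m_max))
      m_max <- find_saturation_intensity(sp, search_cfg, "cat_frequency")
    make_scenario(kind, m_max = m_max, grid_step = grid_step)
  } else if (kind == "egg_harvest") {
    make_scenario(kind, sp, search_cfg, n_points = n_points,
                  egg_fraction = egg_fraction)
  } else {
    make_scenario(kind, sp, search_cfg, grid_step = grid_step,
                  n_points = n_points)
  }
}

curves_to_integrals <- function(curves) {
  recs <- lapply(curves, function(cv)
    data.frame(species = cv$species, scenario = cv$kind,
               integral = cv$integral, stringsAsFactors = FALSE))
  long <- do.call(rbind, recs)
  wide <- stats::reshape(long, idvar = "species", timevar = "scenario",
                         direction = "wide")
  names(wide) <- sub("^integral\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

species_info <- function(species) {
  do.call(rbind, lapply(species, function(sp) {
    m <- build_leslie(sp)
    data.frame(species = sp$name, status = sp$status, group = sp$group,
               mass_kg = sp$mass_kg, G = m$G, stringsAsFactors = FALSE)
  }))
}

strip_fit <- function(rr) rr[setdiff(names(rr), "fit")]

#' Command-line interface
#'
#' Entry point behind `inst/cli/paleopva.R`. Subcommands:
#' \describe{
#'   \item{make-fixtures}{write a synthetic species table (and windows) to
#'     CSV.}
#'   \item{sweep}{sweep one scenario for one or all species from a species
#'     CSV; writes a tidy curve CSV.}
#'   \item{pipeline}{run the full pipeline from a species CSV (and optional
#'     windows CSV).}
#' }
#' Run with `--help` after a subcommand for its options. Iterations, grid
#' resolution and the quasi-extinction threshold are overridable so that
#' desk-scale checks and full-scale runs share one code path.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status 0 invisibly; stops on usage errors.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: paleopva.R <make-fixtures|sweep|pipeline> [options]")
  sub <- args[1]
  rest <- args[-1]
  switch(sub,
    "make-fixtures" = cli_make_fixtures(rest),
    "sweep" = cli_sweep(rest),
    "pipeline" = cli_pipeline(rest),
    stop("unknown subcommand: ", sub))
  invisible(0L)
}

cli_common_opts <- function() {
  list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--iterations", type = "integer", default = 500L),
    optparse::make_option("--eq", type = "double", default = 50,
                          help = "quasi-extinction threshold (females)"),
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "JSON/YAML config file (overridden by flags)"))
}

cli_config <- function(opt) {
  cfg <- if (!is.null(opt$config)) read_config(opt$config) else sim_config()
  cfg$iterations <- as.integer(opt$iterations)
  cfg$eq_threshold_females <- opt$eq
  cfg$seed <- opt$seed
  cfg
}

cli_make_fixtures <- function(rest) {
  parser <- optparse::OptionParser(option_list = c(list(
    optparse::make_option("--out", type = "character", default = "species.csv"),
    optparse::make_option("--windows-out", type = "character",
                          dest = "windows_out", default = NULL),
    optparse::make_option("--regime", type = "character", default = "random")),
    list(optparse::make_option("--seed", type = "integer", default = 1L))))
  opt <- optparse::parse_args(parser, args = rest)
  species <- generate_species_table(generator_spec(seed = opt$seed))
  write_species_table(species, opt$out)
  message("wrote ", opt$out)
  if (!is.null(opt$windows_out)) {
    w <- generate_extinction_windows(species, regime = opt$regime,
                                     seed = opt$seed + 1L)
    write_windows(w, opt$windows_out)
    message("wrote ", opt$windows_out)
  }
}

cli_sweep <- function(rest) {
  parser <- optparse::OptionParser(option_list = c(list(
    optparse::make_option("--species", type = "character"),
    optparse::make_option("--name", type = "character", default = NULL,
                          help = "restrict to one species"),
    optparse::make_option("--scenario", type = "character",
                          default = "all_survival"),
    optparse::make_option("--grid-step", type = "double", dest = "grid_step",
                          default = 0.05),
    optparse::make_option("--out", type = "character", default = "curves.csv")),
    cli_common_opts()))
  opt <- optparse::parse_args(parser, args = rest)
  species <- read_species_table(opt$species)
  if (!is.null(opt$name)) species <- species[opt$name]
  cfg <- cli_config(opt)
  curves <- lapply(species, function(sp) {
    settings <- make_scenario(opt$scenario, sp, cfg, grid_step = opt$grid_step)
    sweep_scenario(sp, cfg, settings)
  })
  write_curves(curves, opt$out)
  message("wrote ", opt$out)
}

cli_pipeline <- function(rest) {
  parser <- optparse::OptionParser(option_list = c(list(
    optparse::make_option("--species", type = "character"),
    optparse::make_option("--windows", type = "character", default = NULL),
    optparse::make_option("--out-dir", type = "character", dest = "out_dir",
                          default = "paleopva-results"),
    optparse::make_option("--grid-step", type = "double", dest = "grid_step",
                          default = 0.05)),
    cli_common_opts()))
  opt <- optparse::parse_args(parser, args = rest)
  species <- read_species_table(opt$species)
  windows <- if (!is.null(opt$windows)) read_windows(opt$windows) else NULL
  cfg <- cli_config(opt)
  run_pipeline(species, cfg, out_dir = opt$out_dir, windows = windows,
               grid_step = opt$grid_step)
  message("pipeline results in ", opt$out_dir)
}
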