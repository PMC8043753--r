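#' Species demographic parameter set
#'
#' Bundles one species' complete demographic parameterization: age-specific
#' survival and fertility schedules, age at first breeding, longevity, body
#' mass, population density and the terminal-transition flag. This is the row
#' unit of the whole analysis; every model, projection and scenario starts
#' from one of these.
#'
#' Ages are indexed \eqn{x = 0, \dots, \omega}, so `survival` and `fertility`
#' have length `omega + 1`. `survival[x+1]` is \eqn{S_x}, the probability of
#' surviving from age x to x+1; `fertility[x+1]` is \eqn{m_x}, daughters per
#' female per year produced at age x. Fertility must be zero before `alpha`.
#'
#' `terminal_self_loop` controls the last diagonal element of the projection
#' matrix: `TRUE` keeps \eqn{M[\omega,\omega] = S_\omega} (individuals may
#' remain in the final age class), `FALSE` forces it to 0, used for species
#' where an immortal old-age tail is biologically unrealistic (e.g. wombats
#' and dasyurid carnivores with catastrophic senescence).
#'
#' @param name species label.
#' @param status `"extinct"` or `"extant"`.
#' @param group functional/taxonomic group, one of `"vombatiform"`,
#'   `"macropodiform"`, `"bird"`, `"carnivore"`, `"monotreme"`.
#' @param mass_kg adult female body mass (kg), positive.
#' @param alpha integer age (yr) at first breeding, `1 <= alpha <= omega`.
#' @param omega integer maximum age (yr).
#' @param survival numeric vector of \eqn{S_x \in [0,1]}, length `omega + 1`.
#' @param fertility numeric vector of \eqn{m_x \ge 0} (daughters per female
#'   per year), length `omega + 1`.
#' @param density population density D (individuals per km^2), `>= 0`.
#' @param terminal_self_loop logical, see Details.
#' @return an object of class `species_params`.
#' @examples
#' sp <- species_params("toy", "extant", "macropodiform", mass_kg = 20,
#'                      alpha = 2, omega = 6,
#'                      survival = c(0.5, 0.7, rep(0.8, 5)),
#'                      fertility = c(0, 0, rep(0.6, 5)),
#'                      density = 2)
#' sp
#' @export
species_params <- function(name, status = c("extant", "extinct"),
                           group = c("vombatiform", "macropodiform", "bird",
                                     "carnivore", "monotreme"),
                           mass_kg, alpha, omega, survival, fertility,
                           density, terminal_self_loop = TRUE) {
  status <- match.arg(status)
  group <- match.arg(group)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(mass_kg) || length(mass_kg) != 1L || mass_kg <= 0)
    stop("mass_kg must be a positive scalar for species '", name, "'")
  alpha <- as.integer(alpha); omega <- as.integer(omega)
  if (is.na(alpha) || is.na(omega) || alpha < 1L || alpha > omega)
    stop("need 1 <= alpha <= omega for species '", name, "'")
  k <- omega + 1L
  if (length(survival) != k || length(fertility) != k)
    stop("survival and fertility must have length omega + 1 (= ", k,
         ") for species '", name, "'")
  if (any(!is.finite(survival)) || any(survival < 0) || any(survival > 1))
    stop("survival probabilities must lie in [0, 1] for species '", name, "'")
  if (any(!is.finite(fertility)) || any(fertility < 0))
    stop("fertilities must be finite and >= 0 for species '", name, "'")
  if (alpha >= 1L && any(fertility[seq_len(alpha)] > 0))
    stop("fertility must be 0 for ages below alpha for species '", name, "'")
  if (!is.numeric(density) || length(density) != 1L || density < 0)
    stop("density must be a scalar >= 0 for species '", name, "'")
  structure(list(
    name = name, status = status, group = group, mass_kg = mass_kg,
    alpha = alpha, omega = omega,
    survival = as.numeric(survival), fertility = as.numeric(fertility),
    density = as.numeric(density),
    terminal_self_loop = isTRUE(terminal_self_loop)
  ), class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("<species_params> %s (%s %s)\n", x$name, x$status, x$group))
  cat(sprintf("  mass %.3g kg | alpha %d | omega %d | D %.4g km^-2 | terminal loop: %s\n",
              x$mass_kg, x$alpha, x$omega, x$density,
              if (x$terminal_self_loop) "S_omega" else "0"))
  cat("  S_x:", paste(signif(x$survival, 3), collapse = " "), "\n")
  cat("  m_x:", paste(signif(x$fertility, 3), collapse = " "), "\n")
  invisible(x)
}

#' Read and write species demographic tables
#'
#' The wide format stores one row per species with the survival and fertility
#' schedules as semicolon-delimited lists inside the `survival` and
#' `fertility` cells. The long format splits the schedules into a companion
#' table with columns `name`, `age`, `survival`, `fertility` keyed by species.
#'
#' @param path CSV file path (wide format).
#' @param species list of [species_params()] objects.
#' @return `read_species_table()` returns a named list of `species_params`;
#'   `write_species_table()` invisibly returns `path`.
#' @seealso [read_species_long()] for the long (one row per age) layout.
#' @export
read_species_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "status", "group", "mass_kg", "alpha", "omega",
                "density", "terminal_self_loop", "survival", "fertility")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("species table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    species_params(
      name = row$name, status = row$status, group = row$group,
      mass_kg = row$mass_kg, alpha = row$alpha, omega = row$omega,
      survival = parse_rate_list(row$survival, row$name, "survival", i),
      fertility = parse_rate_list(row$fertility, row$name, "fertility", i),
      density = row$density,
      terminal_self_loop = as.logical(row$terminal_self_loop))
  })
  names(out) <- df$name
  out
}

parse_rate_list <- function(cell, name, what, row) {
  v <- suppressWarnings(as.numeric(strsplit(as.character(cell), ";")[[1]]))
  if (length(v) == 0L || anyNA(v))
    stop("row ", row, " (", name, "): cannot parse ", what,
         " cell as a ;-delimited numeric list")
  v
}

#' @rdname read_species_table
#' @export
write_species_table <- function(species, path) {
  df <- do.call(rbind, lapply(species, function(sp) {
    data.frame(
      name = sp$name, status = sp$status, group = sp$group,
      mass_kg = sp$mass_kg, alpha = sp$alpha, omega = sp$omega,
      density = sp$density, terminal_self_loop = sp$terminal_self_loop,
      survival = paste(format(sp$survival, digits = 17, trim = TRUE,
                              scientific = FALSE), collapse = ";"),
      fertility = paste(format(sp$fertility, digits = 17, trim = TRUE,
                               scientific = FALSE), collapse = ";"),
      stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read species rates split across a metadata and a long-format rates CSV
#'
#' @param meta_path CSV with columns `name`, `status`, `group`, `mass_kg`,
#'   `alpha`, `omega`, `density`, `terminal_self_loop`.
#' @param rates_path CSV with columns `name`, `age`, `survival`, `fertility`,
#'   one row per (species, age), ages 0..omega.
#' @return named list of [species_params()].
#' @export
read_species_long <- function(meta_path, rates_path) {
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  rates <- read.csv(rates_path, stringsAsFactors = FALSE)
  for (col in c("name", "age", "survival", "fertility"))
    if (!col %in% names(rates))
      stop("rates table ", rates_path, " is missing column: ", col)
  out <- lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    r <- rates[rates$name == row$name, ]
    r <- r[order(r$age), ]
    if (nrow(r) != row$omega + 1L || !all(r$age == 0:row$omega))
      stop("rates for species '", row$name, "' must cover ages 0..",
           row$omega, " exactly")
    species_params(
      name = row$name, status = row$status, group = row$group,
      mass_kg = row$mass_kg, alpha = row$alpha, omega = row$omega,
      survival = r$survival, fertility = r$fertility,
      density = row$density,
      terminal_self_loop = as.logical(row$terminal_self_loop))
  })
  names(out) <- meta$name
  out
}
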