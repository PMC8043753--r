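#' Ordinary least squares with an AICc evidence ratio
#'
#' Fits `y ~ x` by OLS and quantifies the evidence for a relationship as the
#' ratio of small-sample-corrected Akaike weights of the slope model versus
#' the intercept-only model:
#' \deqn{ER = \exp\{(AICc_0 - AICc_1)/2\},}
#' where subscripts 0/1 denote intercept-only and slope models. ER > 1
#' favours a relationship; the small-sample correction matters at the
#' n ~ 21 typical of cross-species comparisons. Predictors are typically
#' log10 body mass or log10 generation length.
#'
#' @param x numeric predictor (already log-transformed if desired).
#' @param y numeric response.
#' @return an object of class `regression_result`: `slope`, `intercept`,
#'   `slope_se`, `r_squared`, `evidence_ratio`, `aicc_slope`, `aicc_null`,
#'   `n`, and the underlying `fit`.
#' @export
fit_allometry <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite (x, y) pairs")
  if (length(unique(x)) < 2) stop("zero variance in x: slope undefined")
  fit1 <- lm(y ~ x)
  fit0 <- lm(y ~ 1)
  if (n >= 5) {  # AICc needs n > k + 1 with k = 3 for the slope model
    a1 <- aicc(fit1)
    a0 <- aicc(fit0)
  } else {
    a1 <- NA_real_; a0 <- NA_real_
  }
  sm <- suppressWarnings(summary(fit1))  # tolerate exact fits
  structure(list(
    slope = unname(coef(fit1)[2]), intercept = unname(coef(fit1)[1]),
    slope_se = unname(sm$coefficients[2, 2]),
    r_squared = sm$r.squared,
    evidence_ratio = exp((a0 - a1) / 2),
    aicc_slope = a1, aicc_null = a0, n = n, fit = fit1
  ), class = "regression_result")
}

# small-sample-corrected AIC for an lm fit; k counts all estimated
# parameters including the residual variance
aicc <- function(fit) {
  ll <- as.numeric(logLik(fit))
  k <- attr(logLik(fit), "df")
  n <- length(fit$residuals)
  if (n - k - 1 <= 0) stop("AICc undefined: n <= k + 1")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> n = %d | slope = %.4g (SE %.3g) | R^2 = %.3f | ER = %.4g\n",
    x$n, x$slope, x$slope_se, x$r_squared, x$evidence_ratio))
  invisible(x)
}

#' Extinction-window table constructor/validator
#'
#' Windows are expressed in ka (thousand years) before present, so the
#' earliest bound is the numerically larger one. The midpoint is the
#' arithmetic centre of the window.
#'
#' @param species character vector.
#' @param earliest_ka,latest_ka numeric bounds (earliest >= latest).
#' @return data frame with `species`, `earliest_ka`, `latest_ka`,
#'   `midpoint_ka`.
#' @export
extinction_windows <- function(species, earliest_ka, latest_ka) {
  stopifnot(length(species) == length(earliest_ka),
            length(species) == length(latest_ka))
  if (any(earliest_ka < latest_ka))
    stop("earliest_ka must be >= latest_ka (ka counts backwards in time)")
  data.frame(species = as.character(species),
             earliest_ka = earliest_ka, latest_ka = latest_ka,
             midpoint_ka = (earliest_ka + latest_ka) / 2,
             stringsAsFactors = FALSE)
}

#' Read/write extinction-window CSVs
#' @param path CSV with columns `species`, `earliest_ka`, `latest_ka`.
#' @param windows a data frame from [extinction_windows()].
#' @return `read_windows()` the validated window table;
#'   `write_windows()` invisibly `path`.
#' @export
read_windows <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("species", "earliest_ka", "latest_ka"))
    if (!col %in% names(df))
      stop("windows table ", path, " is missing column: ", col)
  extinction_windows(df$species, df$earliest_ka, df$latest_ka)
}

#' @rdname read_windows
#' @export
write_windows <- function(windows, path) {
  write.csv(windows[c("species", "earliest_ka", "latest_ka")], path,
            row.names = FALSE)
  invisible(path)
}

#' Concordance between extinction chronology and demographic risk
#'
#' Tests whether more demographically susceptible species went extinct
#' earlier: Spearman rank correlation between the risk measure and the
#' extinction-window midpoint (positive = susceptible species have older,
#' i.e. earlier, dates), plus an OLS fit of midpoint on risk with the same
#' AICc evidence-ratio machinery, and optionally a permutation p-value for
#' the rank correlation. Sensitivity fits against the earliest and latest
#' window bounds are included.
#'
#' @param windows window table (see [extinction_windows()]), extinct species
#'   only.
#' @param risk named numeric vector of a risk measure (integral, total risk
#'   or median rank) covering the window species.
#' @param n_perm permutations for the p-value (0 = skip).
#' @return list with `n`, `spearman`, `perm_p` (or `NA`), and
#'   `fit_midpoint`, `fit_earliest`, `fit_latest` regression results.
#' @export
chronology_concordance <- function(windows, risk, n_perm = 0) {
  stopifnot(is.data.frame(windows))
  common <- intersect(windows$species, names(risk))
  if (length(common) < 3)
    stop("need at least 3 extinct species with both a window and a risk value")
  w <- windows[match(common, windows$species), ]
  r <- as.numeric(risk[common])
  rho <- cor(r, w$midpoint_ka, method = "spearman")
  perm_p <- NA_real_
  if (n_perm > 0) {
    null_rho <- replicate(n_perm,
      abs(cor(sample(r), w$midpoint_ka, method = "spearman")))
    perm_p <- (sum(null_rho >= abs(rho)) + 1) / (n_perm + 1)
  }
  list(
    n = length(common), spearman = rho, perm_p = perm_p,
    fit_midpoint = fit_allometry(r, w$midpoint_ka),
    fit_earliest = fit_allometry(r, w$earliest_ka),
    fit_latest = fit_allometry(r, w$latest_ka))
}

#' Refit a regression with labelled points removed
#'
#' Side-by-side full-data and reduced-data fits, for judging the influence
#' of outlying species on an allometric risk relationship.
#'
#' @param x,y regression variables.
#' @param labels per-point species labels.
#' @param drop_labels labels to drop for the reduced fit.
#' @return list with elements `full` and `reduced`, both
#'   [fit_allometry()] results.
#' @export
outlier_sensitivity <- function(x, y, labels, drop_labels = character()) {
  stopifnot(length(x) == length(y), length(labels) == length(x))
  unknown <- setdiff(drop_labels, labels)
  if (length(unknown))
    stop("drop_labels not present in labels: ", paste(unknown, collapse = ", "))
  keep <- !(labels %in% drop_labels)
  if (sum(keep) < 3) stop("dropping those labels leaves fewer than 3 points")
  list(full = fit_allometry(x, y),
       reduced = fit_allometry(x[keep], y[keep]))
}
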