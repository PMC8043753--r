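#' Build a deterministic Leslie projection matrix from species rates
#'
#' Constructs the \eqn{(\omega+1) \times (\omega+1)} female-only annual
#' projection matrix \strong{M}: fertilities occupy the first row, survival
#' probabilities \eqn{S_0, \dots, S_{\omega-1}} the sub-diagonal, and the
#' final diagonal element is \eqn{S_\omega} (a terminal self-loop) unless the
#' species is flagged `terminal_self_loop = FALSE`, in which case it is 0.
#'
#' Under the default pre-breeding census (`census = "pre"`) the first-row
#' entries fold first-year survival into fertility:
#' \eqn{F_x = S_x \, m_{x+1}} (offspring conceived by a mother censused at
#' age x must survive to be counted), with
#' \eqn{F_\omega = S_\omega m_\omega} when the terminal self-loop is present
#' and 0 otherwise. `census = "post-literal"` instead places the raw
#' \eqn{m_x} in row one.
#'
#' The dominant eigenpair gives the asymptotic growth rate \eqn{\lambda} and
#' the stable age distribution \strong{w} (normalized to sum 1). The net
#' reproductive rate \eqn{R_0} is computed from the fundamental matrix,
#' \eqn{R_0 = \mathbf{F}(\mathbf{I}-\mathbf{T})^{-1}} evaluated for a cohort
#' starting at age 0, and the generation length G defaults to the mean age of
#' mothers at the stable age distribution (see [generation_length()]).
#'
#' If the dominant eigenvalue is non-unique in modulus (cyclic, e.g. strictly
#' semelparous life histories), the eigenvalue of largest modulus with
#' positive real part is taken and \strong{w} is averaged over one cycle of
#' the power iteration.
#'
#' @param params a [species_params()] object.
#' @param census `"pre"` (default) or `"post-literal"`, see Details.
#' @param g_method passed to [generation_length()].
#' @return an object of class `leslie_model` with elements `matrix`,
#'   `lambda`, `w`, `R0`, `G`, `census`, and the originating `params`.
#' @examples
#' sp <- species_params("toy", "extant", "carnivore", 10, alpha = 1, omega = 1,
#'                      survival = c(0.5, 0.4), fertility = c(0, 2),
#'                      density = 1, terminal_self_loop = FALSE)
#' m <- build_leslie(sp)
#' m$lambda
#' @export
build_leslie <- function(params, census = c("pre", "post-literal"),
                         g_method = c("abar", "logR0")) {
  stopifnot(inherits(params, "species_params"))
  census <- match.arg(census)
  g_method <- match.arg(g_method)
  k <- params$omega + 1L
  S <- params$survival
  m <- params$fertility

  M <- matrix(0, k, k)
  if (census == "pre") {
    if (k > 1L) M[1, 1:(k - 1L)] <- S[1:(k - 1L)] * m[2:k]
    M[1, k] <- if (params$terminal_self_loop) S[k] * m[k] else 0
  } else {
    M[1, ] <- m
  }
  if (k > 1L) M[cbind(2:k, 1:(k - 1L))] <- S[1:(k - 1L)]
  if (params$terminal_self_loop) M[k, k] <- M[k, k] + S[k]

  if (all(M == 0))
    stop("projection matrix for species '", params$name,
         "' is identically zero; eigenanalysis is degenerate")

  eig <- dominant_eigen(M)
  Fv <- M[1, ]
  R0 <- net_reproductive_rate(M)

  model <- structure(list(
    matrix = M, lambda = eig$lambda, w = eig$w, R0 = R0, G = NA_real_,
    census = census, params = params
  ), class = "leslie_model")
  model$G <- if (R0 > 0) generation_length(model, method = g_method) else NA_real_
  model
}

# Dominant eigenpair; handles cyclic (modulus-tied) spectra by cycle-averaging
# the power iteration for w.
dominant_eigen <- function(M) {
  eig <- eigen(M)
  mods <- Mod(eig$values)
  top <- max(mods)
  if (top < 1e-300) {
    # nilpotent (e.g. no reproduction, no terminal loop): spectral radius 0
    return(list(lambda = 0, w = rep(1 / nrow(M), nrow(M))))
  }
  cand <- which(mods > top * (1 - 1e-9))
  # prefer positive real part among modulus-tied candidates
  pick <- cand[which.max(Re(eig$values[cand]))]
  lambda <- Re(eig$values[pick])
  if (lambda <= 0)
    stop("no dominant eigenvalue with positive real part")
  d <- length(cand)
  if (d == 1L) {
    w <- abs(Re(eig$vectors[, pick]))
  } else {
    # cyclic case: average the normalized power iterates over one cycle
    k <- nrow(M)
    v <- rep(1 / k, k)
    for (i in seq_len(200L)) {
      v <- as.numeric(M %*% v)
      s <- sum(v)
      if (s <= 0) stop("power iteration collapsed to zero")
      v <- v / s
    }
    acc <- numeric(k)
    for (i in seq_len(d)) {
      acc <- acc + v
      v <- as.numeric(M %*% v)
      v <- v / sum(v)
    }
    w <- acc / d
  }
  list(lambda = lambda, w = w / sum(w))
}

# R0 via the fundamental matrix: expected lifetime production of age-0
# daughters by an age-0 female; handles the terminal self-loop exactly.
net_reproductive_rate <- function(M) {
  k <- nrow(M)
  Tm <- M
  Tm[1, ] <- 0
  if (k >= 2L && M[1, 1] != 0) Tm[1, 1] <- 0  # row-1 entries are fertility
  Fv <- M[1, ]
  if (all(Fv == 0)) return(0)
  Nmat <- tryCatch(solve(diag(k) - Tm),
                   error = function(e) NULL)
  if (is.null(Nmat)) return(Inf)  # immortal transition structure
  drop(Fv %*% Nmat[, 1])
}

#' @export
print.leslie_model <- function(x, ...) {
  cat(sprintf("<leslie_model> %s: %d age classes, census = %s\n",
              x$params$name, nrow(x$matrix), x$census))
  cat(sprintf("  lambda = %.6f | R0 = %.4f | G = %.3f yr\n",
              x$lambda, x$R0, x$G))
  invisible(x)
}

#' Stable age distribution of a Leslie model
#'
#' Returns the right eigenvector \strong{w} of the projection matrix
#' associated with the dominant eigenvalue, scaled to sum to one: the
#' long-run proportional age structure toward which repeated projection of
#' any positive starting vector converges.
#'
#' @param model a [build_leslie()] result.
#' @return numeric vector of length \eqn{\omega + 1}, non-negative, summing
#'   to 1.
#' @export
stable_structure <- function(model) {
  stopifnot(inherits(model, "leslie_model"))
  model$w
}

#' Generation length from a Leslie model
#'
#' Default method `"abar"` is the mean age of mothers of offspring produced
#' at the stable age distribution,
#' \deqn{G = \sum_x x \lambda^{-x} l_x m_x / \sum_x \lambda^{-x} l_x m_x,}
#' with survivorship \eqn{l_x = \prod_{i<x} S_i}. When the terminal age class
#' has a self-loop the sum is extended past \eqn{\omega} along the geometric
#' tail \eqn{S_\omega^k} until terms are negligible. Method `"logR0"` returns
#' \eqn{\log R_0 / \log \lambda} (falling back to `"abar"` when
#' \eqn{\lambda \approx 1}, where it is undefined).
#'
#' @param model a [build_leslie()] result with \eqn{R_0 > 0}.
#' @param method `"abar"` (default) or `"logR0"`.
#' @return generation length in years, `>= alpha`.
#' @export
generation_length <- function(model, method = c("abar", "logR0")) {
  stopifnot(inherits(model, "leslie_model"))
  method <- match.arg(method)
  p <- model$params
  if (model$R0 <= 0)
    stop("generation length undefined for species '", p$name,
         "': net reproductive rate R0 = 0")
  if (method == "logR0") {
    if (abs(model$lambda - 1) < 1e-8) {
      method <- "abar"
    } else {
      return(log(model$R0) / log(model$lambda))
    }
  }
  lambda <- model$lambda
  S <- p$survival; m <- p$fertility
  ages <- 0:p$omega
  lx <- c(1, cumprod(S))[seq_along(ages)]  # l_0 = 1, l_x = prod_{i<x} S_i
  terms <- lambda^(-ages) * lx * m
  num <- sum(ages * terms); den <- sum(terms)
  if (p$terminal_self_loop && S[p$omega + 1L] > 0 && m[p$omega + 1L] > 0) {
    # geometric tail: survivors held at age omega keep breeding at m_omega
    ratio <- S[p$omega + 1L] / lambda
    if (ratio >= 1)
      stop("divergent old-age tail (S_omega >= lambda) for species '",
           p$name, "'")
    x <- p$omega; term <- terms[length(terms)]
    repeat {
      x <- x + 1L
      term <- term * ratio
      num <- num + x * term
      den <- den + term
      if (term < 1e-12 * den || x > p$omega + 100000L) break
    }
  }
  num / den
}

#' Initial population vector
#'
#' The starting abundance vector is \eqn{n_0 = A \, D \, \mathbf{M w}}: the
#' study-zone area times density gives total abundance, partitioned across
#' ages by the stable age distribution and advanced one step through the
#' matrix (set `premultiply = FALSE` to use \eqn{A D \mathbf{w}} directly).
#'
#' @param params a [species_params()] object.
#' @param model the corresponding [build_leslie()] model.
#' @param area_km2 study-zone surface area; default 250000 km^2
#'   (a 500 km x 500 km zone).
#' @param premultiply logical; apply the extra multiplication by \strong{M}
#'   (default `TRUE`).
#' @return non-negative numeric vector of length \eqn{\omega + 1}. A species
#'   with density 0 yields the zero vector with a warning.
#' @export
initial_population <- function(params, model, area_km2 = 250000,
                               premultiply = TRUE) {
  stopifnot(inherits(params, "species_params"), inherits(model, "leslie_model"))
  if (!is.numeric(area_km2) || area_km2 <= 0) stop("area_km2 must be > 0")
  if (params$density == 0) {
    warning("species '", params$name,
            "' has density 0: initial population is the zero vector")
    return(numeric(params$omega + 1L))
  }
  base <- area_km2 * params$density * model$w
  if (premultiply) as.numeric(model$matrix %*% base) else base
}
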