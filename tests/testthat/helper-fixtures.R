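# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

# the default stated-world community, deterministic under its seed
fixture_species <- function() {
  if (is.null(.fixture_env$species)) {
    .fixture_env$species <- generate_species_table(generator_spec(seed = 42))
  }
  .fixture_env$species
}

fixture_summary <- function() attr(fixture_species(), "summary")

# a small, fast-breeding toy species (short horizon, cheap projections)
toy_species <- function(name = "toy", density = 2, self_loop = TRUE) {
  species_params(name, "extant", "carnivore", mass_kg = 5,
                 alpha = 1, omega = 4,
                 survival = c(0.45, 0.7, 0.7, 0.7, 0.6),
                 fertility = c(0, 1.4, 1.6, 1.6, 1.2),
                 density = density, terminal_self_loop = self_loop)
}

# independent oracle: plain power iteration (no eigen())
power_iteration <- function(M, n_steps = 10000) {
  v <- rep(1 / nrow(M), nrow(M))
  lambda <- NA_real_
  for (i in seq_len(n_steps)) {
    v2 <- as.numeric(M %*% v)
    lambda <- sum(v2)
    v <- v2 / lambda
  }
  list(lambda = lambda, w = v)
}

# independent oracle: branching-process extinction probability by iterating
# the per-individual probability-generating function g(z) of one step
bp_extinction_prob <- function(g, n0, tol = 1e-12, max_iter = 100000) {
  q <- 0
  for (i in seq_len(max_iter)) {
    q_new <- g(q)
    if (abs(q_new - q) < tol) break
    q <- q_new
  }
  q^n0
}

expect_monotone_within_mc <- function(pr, n_iter, label = "") {
  # non-decreasing up to 3 binomial standard errors at the local proportion
  d <- diff(pr)
  p_mid <- pmin(pmax((head(pr, -1) + tail(pr, -1)) / 2, 1e-6), 1 - 1e-6)
  slack <- 3 * sqrt(p_mid * (1 - p_mid) / n_iter)
  expect_true(all(d >= -slack),
              label = paste0(label, ": Pr(E_q) decreases beyond MC noise (",
                             "worst violation ", signif(min(d), 3), ")"))
}
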