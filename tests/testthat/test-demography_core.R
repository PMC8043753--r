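# Leslie matrix construction, eigenanalysis, generation length, n0

test_that("species_params validates its invariants", {
  expect_s3_class(toy_species(), "species_params")
  expect_error(species_params("x", "extant", "bird", 1, alpha = 2, omega = 1,
                              survival = c(0.5, 0.5), fertility = c(0, 1),
                              density = 1),
               "alpha <= omega")
  expect_error(species_params("x", "extant", "bird", 1, alpha = 2, omega = 3,
                              survival = rep(0.5, 4),
                              fertility = c(0, 0.5, 1, 1), density = 1),
               "below alpha")
  expect_error(species_params("x", "extant", "bird", 1, alpha = 1, omega = 3,
                              survival = c(0.5, 1.2, 0.5, 0.5),
                              fertility = rep(0, 4), density = 1),
               "\\[0, 1\\]")
})

test_that("build_leslie lays the matrix out as specified", {
  sp <- toy_species()
  m <- build_leslie(sp)
  M <- m$matrix
  k <- sp$omega + 1
  # sub-diagonal = S_0..S_{omega-1}
  expect_equal(M[cbind(2:k, 1:(k - 1))], sp$survival[1:(k - 1)])
  # pre-breeding first row: S_x * m_{x+1}
  expect_equal(M[1, 1:(k - 1)], sp$survival[1:(k - 1)] * sp$fertility[2:k])
  expect_equal(M[1, k], sp$survival[k] * sp$fertility[k])
  expect_equal(M[k, k], sp$survival[k])
  # everything else zero
  off <- M
  off[1, ] <- 0; off[cbind(2:k, 1:(k - 1))] <- 0; off[k, k] <- 0
  expect_true(all(off == 0))
})

test_that("terminal_self_loop = FALSE forces M[omega, omega] = 0", {
  m <- build_leslie(toy_species(self_loop = FALSE))
  k <- nrow(m$matrix)
  expect_identical(m$matrix[k, k], 0)
  # and the terminal fertility entry loses its self-loop contribution
  expect_identical(m$matrix[1, k], 0)
})

test_that("post-literal census places raw m_x in row one", {
  sp <- toy_species()
  m <- build_leslie(sp, census = "post-literal")
  expect_equal(m$matrix[1, ], sp$fertility)
})

test_that("2x2 dominant eigenvalue matches the characteristic polynomial", {
  sp <- species_params("two", "extant", "carnivore", 3, alpha = 1, omega = 1,
                       survival = c(0.5, 0.4), fertility = c(0, 2),
                       density = 1, terminal_self_loop = FALSE)
  m <- build_leslie(sp)
  # oracle: roots of det(M - lambda I) via polyroot on the explicit 2x2
  # characteristic polynomial lambda^2 - (F0 + d) lambda + (F0 d - F1 S0)
  F0 <- m$matrix[1, 1]; F1 <- m$matrix[1, 2]
  S0 <- m$matrix[2, 1]; d <- m$matrix[2, 2]
  roots <- polyroot(c(F0 * d - F1 * S0, -(F0 + d), 1))
  expect_equal(m$lambda, max(Re(roots)), tolerance = 1e-12)
  # explicit layout check: pre-breeding entry S_0 * m_1 = 1.0
  expect_equal(F0, 0.5 * 2)
  expect_equal(S0, 0.5)
})

test_that("no reproduction gives R0 = 0 and survival-structure lambda", {
  base <- toy_species()
  sterile <- species_params("sterile", "extant", "carnivore", 5,
                            alpha = 1, omega = 4,
                            survival = base$survival,
                            fertility = rep(0, 5), density = 1,
                            terminal_self_loop = TRUE)
  m <- build_leslie(sterile)
  expect_equal(m$R0, 0)
  expect_equal(m$lambda, base$survival[5])  # terminal self-loop dominates
  no_loop <- species_params("sterile2", "extant", "carnivore", 5,
                            alpha = 1, omega = 4,
                            survival = base$survival,
                            fertility = rep(0, 5), density = 1,
                            terminal_self_loop = FALSE)
  m2 <- build_leslie(no_loop)
  expect_equal(m2$lambda, 0)  # nilpotent aging chain
  expect_equal(m2$R0, 0)
})

test_that("stable_structure is the normalized dominant eigenvector", {
  m <- build_leslie(toy_species())
  w <- stable_structure(m)
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))
  expect_equal(as.numeric(m$matrix %*% w), m$lambda * w, tolerance = 1e-10)
  # power-iteration oracle
  pi_res <- power_iteration(m$matrix, 1000)
  expect_equal(w, pi_res$w, tolerance = 1e-8)
})

test_that("cyclic 2x2 permutation matrix averages w over the cycle", {
  # [[0,1],[1,0]]: built from S_0 = 1, m_1 = 1, post-literal census
  sp <- species_params("cyc", "extant", "bird", 1, alpha = 1, omega = 1,
                       survival = c(1, 0), fertility = c(0, 1), density = 1,
                       terminal_self_loop = FALSE)
  m <- build_leslie(sp, census = "post-literal")
  expect_equal(m$matrix, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(m$lambda, 1)
  expect_equal(stable_structure(m), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("eigen quantities agree with the power-iteration oracle on every fixture species", {
  for (sp in fixture_species()) {
    m <- build_leslie(sp)
    o <- power_iteration(m$matrix, 10000)
    expect_equal(m$lambda, o$lambda, tolerance = 1e-8, label = sp$name)
    expect_equal(m$w, o$w, tolerance = 1e-8, label = sp$name)
  }
})

test_that("generation length: semelparous, brute-force and boundary cases", {
  # reproduction only at age 3 -> G = 3
  sem <- species_params("sem", "extant", "bird", 2, alpha = 3, omega = 3,
                        survival = c(0.8, 0.8, 0.8, 0),
                        fertility = c(0, 0, 0, 5), density = 1,
                        terminal_self_loop = FALSE)
  expect_equal(build_leslie(sem)$G, 3, tolerance = 1e-12)

  # alpha = omega = 1 -> G = 1
  one <- species_params("one", "extant", "carnivore", 2, alpha = 1, omega = 1,
                        survival = c(0.5, 0), fertility = c(0, 3), density = 1,
                        terminal_self_loop = FALSE)
  expect_equal(build_leslie(one)$G, 1, tolerance = 1e-12)

  # iteroparous: term-by-term direct summation oracle
  it <- species_params("iter", "extant", "macropodiform", 10,
                       alpha = 1, omega = 5,
                       survival = rep(0.8, 6), fertility = c(0, rep(1, 5)),
                       density = 1, terminal_self_loop = FALSE)
  m <- build_leslie(it)
  lam <- m$lambda
  lx <- c(1, cumprod(it$survival))[1:6]
  terms <- lam^-(0:5) * lx * it$fertility
  expect_equal(m$G, sum((0:5) * terms) / sum(terms), tolerance = 1e-10)

  # R0 = 0 -> G undefined
  sterile <- species_params("st", "extant", "carnivore", 5, alpha = 1,
                            omega = 4, survival = rep(0.5, 5),
                            fertility = rep(0, 5), density = 1)
  expect_error(generation_length(build_leslie(sterile)), "R0 = 0")
})

test_that("initial population n0 = A D M w, with flags and degenerate cases", {
  sp <- toy_species()
  m <- build_leslie(sp)
  n0 <- initial_population(sp, m, area_km2 = 250000)
  expect_equal(n0, as.numeric(m$matrix %*% (250000 * sp$density * m$w)))
  # dropping the premultiplication gives A D w
  expect_equal(initial_population(sp, m, 250000, premultiply = FALSE),
               250000 * sp$density * m$w)
  # linearity in area
  expect_equal(initial_population(sp, m, 500000), 2 * n0)
  # zero density -> zero vector with warning
  sp0 <- toy_species(density = 0)
  expect_warning(n00 <- initial_population(sp0, build_leslie(sp0)),
                 "density 0")
  expect_equal(n00, numeric(5))
})

test_that("scaling density scales n0 but leaves lambda, w, G unchanged", {
  sp1 <- toy_species(density = 2)
  sp3 <- toy_species(density = 6)
  m1 <- build_leslie(sp1); m3 <- build_leslie(sp3)
  expect_equal(m1$lambda, m3$lambda)
  expect_equal(m1$w, m3$w)
  expect_equal(m1$G, m3$G)
  expect_equal(initial_population(sp3, m3), 3 * initial_population(sp1, m1))
})
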