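# synthetic community generator and extinction windows

test_that("the default community matches the stated world", {
  spp <- fixture_species()
  s <- fixture_summary()
  expect_length(spp, 21)
  expect_equal(sum(s$status == "extinct"), 13)
  expect_equal(sum(s$status == "extant"), 8)
  expect_equal(as.vector(table(s$group)[c("vombatiform", "macropodiform",
                                          "bird", "carnivore", "monotreme")]),
               c(5, 7, 3, 4, 2))
  expect_true(all(s$mass_kg >= 1.5 & s$mass_kg <= 4000))
  # every extant group represented
  expect_true(all(table(s$group[s$status == "extant"]) >= 1))
  # exactly three no-terminal-self-loop species
  expect_equal(sum(!vapply(spp, `[[`, logical(1), "terminal_self_loop")), 3)
})

test_that("every generated species builds and is near-stationary", {
  s <- fixture_summary()
  expect_true(all(s$lambda >= 0.95 & s$lambda <= 1.10))
  expect_true(all(is.finite(s$G) & s$G > 0))
  expect_true(all(s$alpha >= 1 & s$alpha <= s$omega))
  for (sp in fixture_species()) {
    expect_equal(length(sp$survival), sp$omega + 1, label = sp$name)
    expect_true(all(sp$fertility[seq_len(sp$alpha)] == 0), label = sp$name)
  }
})

test_that("generation is deterministic under a seed, exact in the noiseless limit", {
  a <- generate_species_table(generator_spec(seed = 7))
  b <- generate_species_table(generator_spec(seed = 7))
  expect_identical(attr(a, "summary"), attr(b, "summary"))
  # noiseless: rates are deterministic functions of mass; the mass-G
  # allometry is recovered essentially exactly
  nl <- generate_species_table(generator_spec(seed = 1, noise_sd = 0))
  s <- attr(nl, "summary")
  f <- fit_allometry(log10(s$mass_kg), log10(s$G))
  expect_gt(f$r_squared, 0.9)
})

test_that("the configured mass-G exponent is recoverable downstream", {
  s <- fixture_summary()
  # the configured allometry acts on the target generation length; regress
  # within the mammal groups sharing the default coefficient
  mam <- s[!s$group %in% c("bird", "monotreme"), ]
  f <- fit_allometry(log10(mam$mass_kg), log10(mam$G_target))
  expect_lt(abs(f$slope - 0.25), 2 * f$slope_se)
  # realized G (mean mother age) tracks the target closely despite the
  # integer rounding of alpha and omega
  fr <- fit_allometry(log10(mam$G_target), log10(mam$G))
  expect_gt(fr$r_squared, 0.95)
})

test_that("species tables round-trip through the wide CSV exactly", {
  spp <- fixture_species()
  path <- withr::local_tempfile(fileext = ".csv")
  write_species_table(spp, path)
  back <- read_species_table(path)
  expect_equal(back, spp[names(back)], ignore_attr = TRUE)
})

test_that("long-format reader agrees with the wide reader", {
  spp <- fixture_species()[1:3]
  meta <- withr::local_tempfile(fileext = ".csv")
  rates <- withr::local_tempfile(fileext = ".csv")
  meta_df <- do.call(rbind, lapply(spp, function(sp)
    data.frame(name = sp$name, status = sp$status, group = sp$group,
               mass_kg = sp$mass_kg, alpha = sp$alpha, omega = sp$omega,
               density = sp$density,
               terminal_self_loop = sp$terminal_self_loop)))
  rates_df <- do.call(rbind, lapply(spp, function(sp)
    data.frame(name = sp$name, age = 0:sp$omega, survival = sp$survival,
               fertility = sp$fertility)))
  write.csv(meta_df, meta, row.names = FALSE)
  write.csv(rates_df, rates, row.names = FALSE)
  back <- read_species_long(meta, rates)
  expect_equal(back, spp, ignore_attr = TRUE)
})

test_that("extinction windows respect range, regime and ordering guarantees", {
  spp <- fixture_species()
  s <- fixture_summary()
  risk <- setNames(s$mass_kg^0.3 * (1 + 0.01 * seq_len(nrow(s))), s$name)

  w <- generate_extinction_windows(spp, regime = "risk_ordered", risk = risk,
                                   seed = 11)
  expect_equal(nrow(w), 13)
  expect_true(all(w$earliest_ka <= 60 & w$latest_ka >= 3))
  expect_true(all(w$earliest_ka >= w$latest_ka))
  cc <- chronology_concordance(w, risk)
  expect_gt(cc$spearman, 0.8)  # susceptible species extinct earlier

  wm <- generate_extinction_windows(spp, regime = "mass_ordered", seed = 11)
  mass <- setNames(s$mass_kg, s$name)[wm$species]
  expect_gt(cor(mass, wm$midpoint_ka, method = "spearman"), 0.8)

  # random regime: no relationship on average
  rhos <- vapply(1:100, function(i) {
    wr <- generate_extinction_windows(spp, regime = "random", seed = 1000 + i)
    abs(chronology_concordance(wr, risk)$spearman)
  }, numeric(1))
  expect_lt(median(rhos), 0.3)

  expect_error(generate_extinction_windows(spp, regime = "risk_ordered"),
               "needs a risk vector")
})
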