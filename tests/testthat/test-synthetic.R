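test_that("plating is unbiased and respects its dilution granularity", {
  pm <- plating_model(dilution = 20)
  set.seed(2)
  obs <- plate_counts(rep(500, 20000), pm)
  expect_true(all(obs %% 20 == 0))
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - 500), 3 * se)
  # noiseless switch passes truth through
  expect_equal(plate_counts(c(0, 7, 123), plating_model(poisson = FALSE)),
               c(0, 7, 123))
})

test_that("generators are seed-deterministic", {
  spec <- cohort_spec(densities = c(1e6, 1e8), n_worms = 6, duration = 48,
                      params = canon_params(K = 1e4), seed = 5)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  g1 <- generate_growth_series(0.0625, 2e5, 100, c(0, 24, 48), seed = 9)
  g2 <- generate_growth_series(0.0625, 2e5, 100, c(0, 24, 48), seed = 9)
  expect_identical(g1, g2)
})

test_that("noise-free cohort export equals the simulation truth", {
  spec <- cohort_spec(densities = 1e8, n_worms = 8, duration = 48,
                      params = canon_params(K = 1e4),
                      plating = plating_model(dilution = 1,
                                              poisson = FALSE),
                      seed = 3)
  tab <- generate_cohort(spec)
  expect_equal(tab$obs_strain_1, tab$strain_1)
  expect_equal(tab$obs_fraction, tab$fraction)
  expect_equal(unique(tab$c), density_to_colonization(1e8))
})

test_that("blind export hides truth without changing observables", {
  spec <- cohort_spec(densities = 1e7, n_worms = 8, duration = 48,
                      params = canon_params(K = 1e4), seed = 7)
  full <- generate_cohort(spec)
  blind <- generate_cohort(spec, blind = TRUE)
  expect_false(any(c("strain_1", "total", "fraction") %in% names(blind)))
  expect_identical(blind$obs_fraction, full$obs_fraction)
})

test_that("growth-series generator hits its degenerate and binomial limits", {
  tt <- seq(0, 96, by = 24)
  exact <- generate_growth_series(0.0625, 2e5, 100, tt,
                                  n_worms_per_time = 2, sigma_log10 = 0,
                                  extinct_prob = 0,
                                  plating = plating_model(poisson = FALSE),
                                  seed = 1)
  expect_equal(exact$cfu_per_worm,
               logistic_solution(100, 0.0625, 2e5, exact$time_h))

  # ~20% of worms uncolonized at t = 0 when extinct_prob = 0.2
  # (plating noise off so zeros are exactly the extinctions)
  big <- generate_growth_series(0.0625, 2e5, 100, 0,
                                n_worms_per_time = 4000,
                                plating = plating_model(poisson = FALSE),
                                seed = 6)
  p0 <- mean(big$cfu_per_worm == 0)
  expect_lt(abs(p0 - 0.2), 3 * sqrt(0.2 * 0.8 / 4000))
})

test_that("arrest-series generator decays exponentially", {
  flat <- generate_arrest_series(0, 1000, c(0, 24, 48),
                                 plating = plating_model(poisson = FALSE),
                                 seed = 2)
  expect_true(all(flat$cfu_per_worm == 1000))

  half <- generate_arrest_series(log(2) / 24, 1000, c(0, 24),
                                 plating = plating_model(poisson = FALSE),
                                 seed = 2)
  expect_equal(half$cfu_per_worm[half$time_h == 24] /
                 half$cfu_per_worm[half$time_h == 0], c(0.5, 0.5))

  # round-trip: generate at d = 0.075, estimate within the regression CI
  arr <- generate_arrest_series(0.075, 5e4, c(0, 12, 24, 36, 48),
                                n_digests = 3, seed = 8)
  f <- estimate_death_rate(arr)
  expect_true(f$ci[1, "d"] <= 0.075 && 0.075 <= f$ci[2, "d"])
  expect_equal(unname(f$estimates["d"]), 0.075, tolerance = 0.1)
})

test_that("short-assay generator is linear in density and time", {
  syn <- generate_short_assay(1e-7, c(1e6, 1e8), times = c(1, 4),
                              n_worms_batch = 500, seed = 4)
  expect_equal(nrow(syn), 4)
  at0 <- generate_short_assay(1e-7, 1e8, times = c(0, 4), seed = 4)
  expect_equal(at0$mean_cfu_per_worm[at0$time_h == 0], 0)
  # mean at 1e6 x 4 h is 0.4 CFU/worm
  many <- generate_short_assay(1e-7, 1e6, times = 4,
                               n_worms_batch = 50000, seed = 10)
  expect_equal(many$mean_cfu_per_worm, 0.4, tolerance = 0.05)
})
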