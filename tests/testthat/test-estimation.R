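test_that("noiseless logistic points are recovered to < 1%", {
  tt <- seq(0, 240, by = 24)
  ser <- data.frame(time_h = rep(tt, each = 3),
                    cfu_per_worm = logistic_solution(10, 0.0625, 2e5,
                                                     rep(tt, each = 3)))
  est <- fit_logistic(ser, n_boot = 0)$estimates
  expect_equal(unname(est["r"]), 0.0625, tolerance = 0.01)
  expect_equal(unname(est["K"]), 2e5, tolerance = 0.01)
})

test_that("logistic fit is scale-equivariant in the noiseless case", {
  tt <- seq(0, 240, by = 24)
  ser <- data.frame(time_h = tt,
                    cfu_per_worm = logistic_solution(50, 0.05, 1e5, tt))
  e1 <- fit_logistic(ser, n_boot = 0)$estimates
  ser10 <- transform(ser, cfu_per_worm = cfu_per_worm * 10)
  e10 <- fit_logistic(ser10, n_boot = 0)$estimates
  expect_equal(unname(e10["K"] / e1["K"]), 10, tolerance = 1e-3)
  expect_equal(unname(e10["r"]), unname(e1["r"]), tolerance = 1e-3)
})

test_that("fit_logistic rejects unusable series", {
  expect_error(fit_logistic(data.frame(time_h = c(0, 24, 48, 72),
                                       cfu_per_worm = rep(0, 4))),
               "zero")
  expect_error(fit_logistic(data.frame(time_h = c(0, 24),
                                       cfu_per_worm = c(1, 10))),
               "4 distinct")
})

test_that("parameter recovery on the validation design", {
  # point-estimate accuracy over many synthetic series
  g <- growth_design
  err <- vapply(1:60, function(s) {
    ser <- generate_growth_series(g$r, g$K, g$N0, g$times,
                                  n_worms_per_time = g$n_worms,
                                  seed = 4000 + s)
    est <- fit_logistic(ser, n_boot = 0)$estimates
    c(abs(est["r"] - g$r) / g$r, abs(est["K"] - g$K) / g$K)
  }, numeric(2))
  expect_lt(median(err[1, ]), 0.25)
  expect_lt(median(err[2, ]), 0.15)
})

test_that("bootstrap CIs cover truth at close to nominal rate", {
  g <- growth_design
  cover <- vapply(1:40, function(s) {
    ser <- generate_growth_series(g$r, g$K, g$N0, g$times,
                                  n_worms_per_time = g$n_worms,
                                  seed = 5000 + s)
    f <- fit_logistic(ser, n_boot = 150, seed = s)
    c(f$ci[1, "r"] <= g$r & g$r <= f$ci[2, "r"],
      f$ci[1, "K"] <= g$K & g$K <= f$ci[2, "K"])
  }, logical(2))
  expect_gte(mean(cover[1, ]), 0.85)
  expect_gte(mean(cover[2, ]), 0.85)
})

test_that("death rate: closed forms and recovery from pure-death data", {
  f <- estimate_death_rate(data.frame(time_h = c(0, 24),
                                      cfu_per_worm = c(100, 50)))
  expect_equal(unname(f$estimates["d"]), log(2) / 24, tolerance = 1e-10)

  expect_warning(
    flat <- estimate_death_rate(data.frame(time_h = c(0, 24, 48),
                                           cfu_per_worm = c(80, 80, 80))),
    "d <= 0")
  expect_equal(unname(flat$estimates["d"]), 0)

  # bulk digests of a pure-death process: N(t) ~ Binomial(N0, e^{-dt})
  set.seed(77)
  for (d_true in c(0.05, 0.1, 0.5)) {
    tt <- if (d_true >= 0.5) c(0, 4, 8) else c(0, 24, 48)
    reps <- 6
    draws <- vapply(tt, function(t)
      mean(pure_death_draw(5000, d_true, rep(t, reps))), numeric(1))
    arr <- data.frame(time_h = tt, cfu_per_worm = draws)
    d_hat <- unname(estimate_death_rate(arr)$estimates["d"])
    # SE of the log-slope from binomial counting noise
    se <- sqrt(sum(1 / (exp(-d_true * tt) * 5000 * reps))) / diff(range(tt))
    expect_lt(abs(d_hat - d_true), 3 * se + 0.002)
  }
})

test_that("colonization rate and kappa come back from short assays", {
  a <- data.frame(density_cfu_ml = 1e6, time_h = 4, mean_cfu_per_worm = 0.4)
  f <- suppressMessages(estimate_colonization_rate(a))
  expect_equal(unname(f$estimates["c_1e+06"]), 0.1)
  expect_true(f$single_timepoint[["c_1e+06"]])

  b <- data.frame(density_cfu_ml = rep(c(1e6, 1e9), each = 2),
                  time_h = rep(c(1, 4), 2),
                  mean_cfu_per_worm = c(0.1, 0.4, 100, 400))
  fb <- estimate_colonization_rate(b)
  expect_equal(unname(fb$estimates["kappa"]), 1e-7, tolerance = 1e-10)

  syn <- generate_short_assay(1e-7, densities = 10^(6:9),
                              n_worms_batch = 200, seed = 14)
  fs <- estimate_colonization_rate(syn)
  expect_equal(unname(fs$estimates["kappa"]), 1e-7, tolerance = 0.2)
})

test_that("feeding rate arithmetic and establishment fraction", {
  f <- estimate_feeding_rate(1e6, 9.5e5, hours = 10, n_worms = 1000,
                             c = 0.1)
  expect_equal(f$feeding_rate, 5)
  expect_equal(f$establishment_fraction, 0.02)
  expect_equal(estimate_feeding_rate(1e6, 1e6, 10, 100)$feeding_rate, 0)
  expect_error(estimate_feeding_rate(1e6, 2e6, 10, 100), "increased")
})
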