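test_that("absorbing states are respected", {
  # all rates zero: empty state is absorbing
  p0 <- model_params(b = 0, d = 0, c = 0, K = 1e5)
  expect_identical(unname(simulate_host(p0, 192, seed = 3)$final), c(0, 0))

  # pure death from a seeded state is absorbing at zero
  pd <- model_params(b = 0, d = 0.5, c = 0, K = 1e5)
  tr <- simulate_host(pd, 60, seed = 5, init = c(100, 100))
  expect_identical(unname(tr$final), c(0, 0))

  # and its decay matches the exact Binomial(N0, e^{-dt}) law
  finals <- vapply(1:400, function(i)
    simulate_host(pd, 4, seed = derive_seed(8, i), init = c(100, 0),
                  method = "exact")$final[1], numeric(1))
  set.seed(21)
  oracle <- pure_death_draw(100, 0.5, rep(4, 400))
  se <- sqrt(var(finals) / 400 + var(oracle) / 400)
  expect_lt(abs(mean(finals) - mean(oracle)), 3 * se)
})

test_that("identical (params, seed, method) give identical output", {
  p <- canon_params(c = 0.5, K = 1e4)
  a <- simulate_host(p, 96, seed = 42, record = "path")
  b <- simulate_host(p, 96, seed = 42, record = "path")
  expect_identical(a$counts, b$counts)
  e1 <- simulate_ensemble(p, 10, 96, base_seed = 7)
  e2 <- simulate_ensemble(p, 10, 96, base_seed = 7)
  expect_identical(e1, e2)
})

test_that("ensemble bookkeeping: zero-colonization and neutral symmetry", {
  pz <- model_params(b = 0.6, d = 0.54, c = 0, K = 1e5)
  ez <- simulate_ensemble(pz, 50, 48, base_seed = 1)
  expect_true(all(ez$total == 0))
  expect_true(all(is.na(ez$fraction)))

  # label-exchange symmetry: with neutral strains the strain-2 fraction is
  # exactly 1 - fraction wherever composition is defined
  p <- canon_params(c = 0.3, K = 1e4)
  en <- simulate_ensemble(p, 40, 96, base_seed = 11)
  ok <- en$total > 0
  expect_equal(en$strain_2[ok] / en$total[ok], 1 - en$fraction[ok])

  # neutral mean fraction near 1/2
  p6 <- canon_params(c = 10, K = 1e4)
  e6 <- simulate_ensemble(p6, 200, 96, base_seed = 13)
  f <- cohort_fractions(e6)
  expect_lt(abs(mean(f) - 0.5), 3 * sd(f) / sqrt(length(f)))
})

test_that("ensemble mean matches the linear BDI solution at very large K", {
  p <- model_params(b = 0.6, d = 0.54, c = 0.1, K = 1e9, n_strains = 1)
  finals <- vapply(1:5000, function(i)
    simulate_host(p, 24, seed = derive_seed(17, i))$final[1], numeric(1))
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - linear_bdi_mean(0.1, 0.6, 0.54, 24)), 3 * se)
})

test_that("saturation caps totals and the long-run mean hits the fixed point", {
  p <- canon_params(c = 100, K = 1e4)
  e <- simulate_ensemble(p, 300, 192, base_seed = 19)
  # hard cap up to one tau-leap burst (leap condition: ~3% of state)
  expect_true(all(e$total <= 1e4 * 1.05))
  se <- sd(e$total) / sqrt(nrow(e))
  expect_lt(abs(mean(e$total) - stationary_total(p)), 4 * se)
})

test_that("founding-lineage extinction frequency approaches d/b", {
  p <- model_params(b = 0.6, d = 0.54, c = 0, K = 1e9, n_strains = 1)
  ext <- vapply(1:2000, function(i)
    simulate_host(p, 120, seed = derive_seed(23, i), init = 1)$final == 0,
    logical(1))
  expect_lt(abs(mean(ext) - 0.9), 3 * sqrt(0.9 * 0.1 / 2000))
})

test_that("exact SSA and tau-leap endpoint distributions agree", {
  p <- canon_params(c = 1, K = 1e4)
  e1 <- simulate_ensemble(p, 1000, 48, base_seed = 31, method = "exact")
  e2 <- simulate_ensemble(p, 1000, 48, base_seed = 32, method = "tau")
  D <- unname(suppressWarnings(ks.test(e1$total, e2$total)$statistic))
  expect_lt(D, 1.628 * sqrt(2 / 1000))  # 1% critical value
})

test_that("path recording snapshots are consistent with the endpoint", {
  p <- canon_params(c = 0.5, K = 1e4)
  tr <- simulate_host(p, 96, seed = 2, record = "path")
  expect_equal(nrow(tr$counts), 513)
  expect_true(all(tr$counts >= 0))
  expect_equal(unname(tr$counts[nrow(tr$counts), ]), unname(tr$final))
  tr2 <- simulate_host(p, 96, seed = 2, times = c(0, 48, 96))
  expect_identical(unname(tr2$counts[1, ]), c(0, 0))
})
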