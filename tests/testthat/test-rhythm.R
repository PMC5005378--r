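test_that("periodogram pins the generating period and ignores affine scale", {
  sch <- make_schedule(22, 0.5, 14)
  act <- simulate_activity(sch, 22, seed = 5)
  pg <- chi2_periodogram(act$distance, bin_min = 1)
  expect_lt(abs(attr(pg, "peak_period_h") - 22), 1 / 60 + 1e-9)
  expect_true(pg$significant[which.max(pg$Qp)])
  # affine invariance of Qp
  pg2 <- chi2_periodogram(3 * act$distance + 7, bin_min = 1)
  expect_equal(pg2$Qp, pg$Qp, tolerance = 1e-10)
  # constant series: guarded to zero
  pgc <- chi2_periodogram(rep(5, 2000), bin_min = 10)
  expect_true(all(pgc$Qp == 0))
  expect_error(chi2_periodogram(rnorm(100), bin_min = 1, period_range_h = c(16, 32)),
               "half the data span")
  expect_error(chi2_periodogram(rnorm(10000), bin_min = 120,
                                period_range_h = c(0.5, 1)), "finer")
})

test_that("actogram folding preserves values and pads the last cycle", {
  sch <- make_schedule(21, 0.5, 7)
  act <- simulate_activity(sch, 21, seed = 2)
  m <- actogram_matrix(act, 21)
  expect_equal(dim(m), c(8, 21 * 60))      # 7 x 24 h = exactly 8 cycles
  expect_equal(as.numeric(t(m))[seq_along(act$distance)], act$distance)
  m22 <- actogram_matrix(act, 22)          # incomplete last cycle padded
  expect_equal(dim(m22), c(8, 22 * 60))
  expect_true(all(is.na(m22[8, (ncol(m22) - 10):ncol(m22)])))
  expect_equal(sum(!is.na(m22)), length(act$distance))
})

test_that("cosinor recovers noise-free parameters exactly and scales linearly", {
  t <- seq(0, 48, by = 1 / 6)
  y <- 2 + cos(2 * pi / 24 * t + 40 * pi / 180)
  f <- cosinor_fit(t, y, 24)
  expect_equal(f$M, 2, tolerance = 1e-9)
  expect_equal(f$amplitude, 1, tolerance = 1e-9)
  expect_equal(f$theta_deg, 40, tolerance = 1e-9)
  expect_equal(f$acrophase_lag_deg, 320, tolerance = 1e-9)
  # (beta, gamma) <-> (A, theta) round-trip
  expect_equal(f$beta, f$amplitude * cos(f$theta_deg * pi / 180), tolerance = 1e-9)
  expect_equal(f$gamma, -f$amplitude * sin(f$theta_deg * pi / 180), tolerance = 1e-9)
  # doubling doubles M and A, leaves theta
  f2 <- cosinor_fit(t, 2 * y, 24)
  expect_equal(c(f2$M, f2$amplitude), c(4, 2), tolerance = 1e-9)
  expect_equal(f2$theta_deg, 40, tolerance = 1e-6)
  # singular design
  expect_error(cosinor_fit(rep(c(0, 24, 48), 3), rnorm(9), 24), "singular")
})

test_that("cosinor zero-amplitude p-values are uniform under the null", {
  set.seed(19)
  t <- seq(0, 48, by = 1 / 6)
  ps <- replicate(400, cosinor_fit(t, rnorm(length(t)), 24)$p_zero_amplitude)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("group cosinor collapses correctly for identical subjects", {
  t <- seq(0, 48, by = 1 / 6)
  mk <- function(A, th, eps) cosinor_fit(t, 1 + A * cos(2 * pi / 24 * t + th * pi / 180) +
                                           eps, 24)
  set.seed(4)
  fits <- lapply(1:5, function(i) mk(1, 40, rnorm(length(t), sd = 1e-6)))
  gc <- group_cosinor(list(base = fits))
  expect_equal(gc$estimates$amplitude, 1, tolerance = 1e-4)
  expect_equal(gc$estimates$theta_deg, 40, tolerance = 1e-3)
  expect_lt(gc$estimates$p_zero_amplitude, 1e-6)
  # mixed angular frequencies refuse to combine
  bad <- lapply(1:3, function(i) cosinor_fit(t, rnorm(length(t)), 22))
  expect_error(group_cosinor(list(a = fits, b = bad)), "angular frequency")
  expect_error(group_cosinor(list(a = fits[1:2])), ">= 3")
})

test_that("group cosinor separates rhythmic from arrhythmic conditions", {
  t <- seq(0, 48, by = 1 / 6)
  set.seed(23)
  mk <- function(A) lapply(1:6, function(i)
    cosinor_fit(t, 1 + A * cos(2 * pi / 24 * t + 0.7) + rnorm(length(t), sd = 0.5), 24))
  hits <- replicate(30, {
    gc <- group_cosinor(list(rhythmic = mk(1), flat = mk(0)))
    c(rhythm_sig = gc$estimates$p_zero_amplitude[1] < 0.05,
      diff_sig = gc$pairwise$p[1] < 0.05,
      covers = cosinor_region_covers(gc, "rhythmic", 1, 0.7 * 180 / pi))
  })
  expect_gt(mean(hits["rhythm_sig", ]), 0.9)
  expect_gt(mean(hits["diff_sig", ]), 0.8)       # power for A = 1 vs A = 0
  expect_gt(mean(hits["covers", ]), 0.75)        # ~95% nominal coverage
})
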