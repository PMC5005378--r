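test_that("decay fit recovers exact parameters and is scale-equivariant", {
  t <- seq(0.05, 6, by = 0.1)
  y <- 2 * exp(-t / 1) + 1
  f <- swa_decay_fit(t, y)
  expect_equal(c(f$SWA0, f$tau_h, f$SWAinf), c(2, 1, 1), tolerance = 1e-6)
  expect_false(f$flags$degenerate)
  # scaling SWA by c scales SWA0 and SWAinf, leaves tau
  f3 <- swa_decay_fit(t, 3 * y)
  expect_equal(c(f3$SWA0, f3$SWAinf), 3 * c(f$SWA0, f$SWAinf), tolerance = 1e-5)
  expect_equal(f3$tau_h, f$tau_h, tolerance = 1e-6)
  # flat series: flagged degenerate
  set.seed(2)
  ff <- swa_decay_fit(t, rep(1.5, length(t)) + rnorm(length(t), sd = 1e-3))
  expect_true(ff$flags$degenerate)
  expect_error(swa_decay_fit(1:5, 1:5), ">= 10")
})

test_that("decay recovery from the generator chain stays within 5%", {
  sch <- sch24(1)
  hyp <- new_hypnogram(rep("NREM", 2700), "simulated")   # 3 h pure NREM
  rec <- preprocess(simulate_eeg_emg(hyp, sch, sim_params(noise_sd = 0), seed = 8))
  sw <- swa_nrem_series(rec, hyp, sch, norm = "none")
  f <- swa_decay_fit(sw$t_h, sw$swa)
  expect_lt(abs(f$tau_h - 1) / 1, 0.05)
})

test_that("buildup fit recovers exact parameters and its time covariance", {
  t <- seq(1, 59, by = 2)
  y <- 1 + (3 - 1) / (1 + 10^((log10(20) - log10(t)) * 2))
  f <- buildup_fit(t, y)
  expect_equal(c(f$min, f$max, f$log_t50, f$slope),
               c(1, 3, log10(20), 2), tolerance = 1e-6)
  # rescaling time shifts log_t50 by log10 of the factor, leaves the slope
  f2 <- buildup_fit(t / 10, y)
  expect_equal(f2$log_t50, log10(2), tolerance = 1e-5)
  expect_equal(f2$slope, 2, tolerance = 1e-4)
  # min = max: flagged
  set.seed(3)
  fd <- buildup_fit(t, rep(2, length(t)) + rnorm(length(t), sd = 1e-6))
  expect_true(fd$flags$degenerate)
})

test_that("transition-aligned buildup reproduces the generator's 50-s rise", {
  sch <- sch24(1)
  hyp <- new_hypnogram(rep(c(rep("WAKE", 20), rep("NREM", 30)), 16), "simulated")
  rec <- preprocess(simulate_eeg_emg(hyp, sch, sim_params(noise_sd = 0), seed = 9))
  ts <- transition_swa(rec, hyp)
  expect_gte(ts$n_transitions, 5)
  f <- buildup_fit(ts$mean$t_s, ts$mean$y)
  # fitted curve reaches >= 95% of (max - min) by 50 s
  expect_lte(f$t95_s, 50)
  # too few transitions is an error
  short <- new_hypnogram(rep(c(rep("WAKE", 20), rep("NREM", 30)), 2), "simulated")
  rec2 <- preprocess(simulate_eeg_emg(short, sch, sim_params(noise_sd = 0), seed = 9))
  expect_error(transition_swa(rec2, short), "fewer than 5")
})

test_that("extra-sum-of-squares F test behaves at the boundaries", {
  set.seed(12)
  t <- seq(0.05, 6, by = 0.1)
  y <- 2 * exp(-t) + 1 + rnorm(length(t), sd = 0.05)
  d <- list(t = t, y = y)
  same <- compare_fits_ftest(d, d, model = "decay")
  expect_lt(same$F, 1e-6)
  expect_gt(same$p, 0.99)
  # a genuine amplitude difference is detected
  y2 <- 4 * exp(-t) + 1 + rnorm(length(t), sd = 0.05)
  ft <- compare_fits_ftest(d, list(t = t, y = y2), model = "decay",
                           free = c("SWA0", "SWAinf"))
  expect_equal(ft$df_num, 2L)
  expect_lt(ft$p, 1e-6)
  expect_error(compare_fits_ftest(d, d, model = "decay", free = "bogus"),
               "unknown parameter")
})
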