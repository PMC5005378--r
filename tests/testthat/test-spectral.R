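test_that("state spectra peak at the driving frequency and normalize away scale", {
  rec <- sine_recording(10, 60)
  hyp <- new_hypnogram(rep("WAKE", 15), "simulated")
  sp <- state_spectra(rec, hyp, sch24())
  w <- sp$WAKE
  expect_false(w$missing)
  expect_lt(abs(w$freqs[which.max(w$psd)] - 10), 200 / 512)
  # absent states are flagged missing
  expect_true(sp$REM$missing)
  # doubling the amplitude leaves the normalized spectrum unchanged
  rec2 <- sine_recording(10, 60, amp = 2)
  sp2 <- state_spectra(rec2, hyp, sch24())
  expect_equal(sp2$WAKE$psd, w$psd, tolerance = 1e-10)
})

test_that("white-noise normalized spectrum is flat across 1-45 Hz", {
  set.seed(13)
  n <- 200 * 2400                       # 40 min
  rec <- new_recording(rnorm(n), numeric(n), fs = 200, schedule = sch24())
  hyp <- new_hypnogram(rep("WAKE", 600), "simulated")
  sp <- state_spectra(rec, hyp, sch24())$WAKE
  sel <- which(sp$freqs >= 1 & sp$freqs <= 45)
  # 3-bin running mean damps single-bin estimation noise before the bound
  sm <- stats::filter(sp$psd[sel], rep(1 / 3, 3))
  sm <- sm[!is.na(sm)]
  flat <- sm / mean(sm)
  expect_lt(max(abs(flat - 1)), 0.10)
})

test_that("filter bank recovers phase and attenuates out-of-band input", {
  rec <- new_recording(cos(2 * pi * 8 * (0:(20 * 200 - 1)) / 200),
                       numeric(20 * 200), fs = 200)
  ab <- filterbank_hilbert(rec, centers = c(8, 20))
  mid <- which(ab$valid)
  mid <- mid[mid > 1000 & mid < 3000]
  # band-8 power approximately constant at (amplitude/2)^2 scale
  p8 <- ab$power[mid, 1]
  expect_lt(stats::sd(p8) / mean(p8), 0.05)
  # band-20 power < 1% of band-8 power
  expect_lt(mean(ab$power[mid, 2]), 0.01 * mean(p8))
  # phase advances 2*pi*8 per second
  ph <- unwrap_phase(ab$phase[mid, 1])
  slope <- stats::coef(stats::lm(ph ~ I((mid - 1) / 200)))[2]
  expect_equal(unname(slope), 2 * pi * 8, tolerance = 1e-3)
  # cos convention: phase ~ 0 at the cosine peak
  peak <- mid[which.max(cos(2 * pi * 8 * (mid - 1) / 200))]
  expect_lt(abs(ab$phase[peak, 1]), 0.2)
  expect_error(filterbank_hilbert(new_recording(numeric(2000), numeric(2000))),
               "filter length")
})

test_that("filter-bank output is insensitive to out-of-band additions", {
  n <- 20 * 200
  t <- (0:(n - 1)) / 200
  base <- new_recording(cos(2 * pi * 8 * t), numeric(n), fs = 200)
  plus <- new_recording(cos(2 * pi * 8 * t) + 2 * cos(2 * pi * 30 * t),
                        numeric(n), fs = 200)
  a <- filterbank_hilbert(base, centers = 8)
  b <- filterbank_hilbert(plus, centers = 8)
  mid <- 1500:2500
  expect_lt(max(abs(b$power[mid, 1] - a$power[mid, 1])) / mean(a$power[mid, 1]),
            0.01)
})

test_that("band sums are Parseval-consistent for broadband noise", {
  set.seed(7)
  n <- 30 * 200
  x <- rnorm(n)
  rec <- new_recording(x, numeric(n), fs = 200)
  ab <- filterbank_hilbert(rec, centers = 3:97)
  mid <- which(ab$valid)
  # mean analytic power per band ~ 2x band variance; total across the bank
  # should approximate twice the broadband variance in 2.5-97.5 Hz
  tot <- sum(colMeans(ab$power[mid, ])) / 2
  frac_band <- (97.5 - 2.5) / 100
  expect_lt(abs(tot - var(x) * frac_band) / (var(x) * frac_band), 0.15)
})

test_that("band power series respects the missing-bin rule", {
  rec <- wake_recording(0.4, minutes = 4)
  hyp <- new_hypnogram(rep(c("WAKE", "NREM"), each = 30), "simulated")
  ab <- filterbank_hilbert(rec, centers = 7:9)
  bp <- band_power_series(ab, c(7, 9), state_mask = state_sample_mask(hyp, "WAKE"),
                          bin_s = 120, norm = "none")
  # first 2-min bin is all WAKE, second is all NREM -> missing, not zero
  expect_true(is.finite(bp$value[1]))
  expect_true(is.na(bp$value[2]))
  # constant mask + norm scaling
  bp_ref <- band_power_series(ab, c(7, 9), bin_s = 120, norm = "median_LD12",
                              norm_ref = 2)
  bp_none <- band_power_series(ab, c(7, 9), bin_s = 120, norm = "none")
  expect_equal(bp_ref$value, bp_none$value / 2)
  expect_error(band_power_series(ab, c(60, 70)), "bands inside")
})

test_that("2-s STFT band power tracks a known sine", {
  rec <- sine_recording(2, 30)
  p <- stft_band_power(rec, c(1, 3), bin_s = 2)
  expect_equal(length(p), 15)
  expect_lt(stats::sd(p) / mean(p), 0.02)
  # out-of-band content is excluded
  expect_lt(mean(stft_band_power(rec, c(7, 9.5), bin_s = 2)) / mean(p), 0.01)
})

test_that("spectra comparison finds injected band differences, not null ones", {
  set.seed(101)
  freqs <- seq(0.39, 50, by = 0.39)
  n_f <- length(freqs)
  base <- matrix(rnorm(6 * n_f, mean = 10), 6, n_f)
  # identical conditions: no suprathreshold cells at all
  same <- compare_spectra(base, base, freqs, n_perm = 200, seed = 2)
  expect_length(same$clusters, 0)
  # independent remeasurement of the same subjects with +30% power in 2-4 Hz
  sel <- freqs >= 2 & freqs <= 4
  eff <- base + matrix(rnorm(6 * n_f, sd = 0.5), 6, n_f)
  eff[, sel] <- eff[, sel] + 3
  res <- compare_spectra(base, eff, freqs, n_perm = 500, seed = 3)
  sig <- Filter(function(cc) cc$significant, res$clusters)
  expect_gte(length(sig), 1)
  hit <- any(vapply(sig, function(cc)
    cc$freq_lo <= 4 && cc$freq_hi >= 2, TRUE))
  expect_true(hit)
})
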