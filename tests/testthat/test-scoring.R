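test_that("epoch features isolate the defining bands", {
  fs <- 200
  t <- (0:(800 * 3 - 1)) / fs
  eeg <- c(sin(2 * pi * 2 * t[1:800]), sin(2 * pi * 8 * t[1:800]), numeric(800))
  rec <- new_recording(eeg, numeric(length(eeg)), fs = fs, schedule = sch24())
  f <- compute_epoch_features(rec)
  expect_gt(f$swa_power[1] / f$total_power[1], 0.9)
  expect_gt(f$theta_power[2] / f$total_power[2], 0.9)
  expect_equal(f$swa_power[3], 0)
  expect_equal(f$total_power[3], 0)
  expect_true(all(f$theta_power <= f$total_power + 1e-12))
})

test_that("the scoring rules apply in order", {
  feats <- data.frame(
    epoch = 0:3,
    swa_power   = c(8, 8, 1, 0),
    theta_power = c(1, 1, 6, 0),
    total_power = c(10, 10, 10, 0),
    emg_rms     = c(5, 0.1, 0.1, 0))
  th <- list(emg_threshold = 1, swa_ratio_threshold = 0.45,
             theta_delta_threshold = 1.5)
  # epoch 0: high EMG -> WAKE despite slow-wave EEG; epoch 1: NREM by SWA
  # ratio; epoch 2: REM after NREM; epoch 3: all-zero -> WAKE with warning
  expect_warning(h <- score_epochs(feats, th), "all-zero")
  expect_equal(as.vector(unclass(h)), c("WAKE", "NREM", "REM", "WAKE"))
  # REM without a preceding NREM context is relabelled WAKE
  feats2 <- feats[c(1, 3, 3, 3), ]; feats2$epoch <- 0:3
  h2 <- score_epochs(feats2, th)
  expect_true(all(unclass(h2) != "REM"))
})

test_that("scoring is a pure per-epoch function (permutation invariant)", {
  set.seed(8)
  feats <- data.frame(epoch = 0:99, swa_power = runif(100, 0, 5),
                      theta_power = runif(100, 0, 5),
                      total_power = runif(100, 5, 10),
                      emg_rms = exp(rnorm(100)))
  th <- list(emg_threshold = 1, swa_ratio_threshold = 0.45,
             theta_delta_threshold = 1.5)
  # compare pre-REM-relabelling rule output under permutation
  raw_rule <- function(f) ifelse(f$emg_rms >= 1, "WAKE",
                          ifelse(f$swa_power / f$total_power >= 0.45, "NREM",
                          ifelse(f$theta_power / f$swa_power >= 1.5, "REM", "NREM")))
  perm <- sample(100)
  expect_identical(raw_rule(feats)[perm], raw_rule(feats[perm, ]))
})

test_that("scored hypnogram recovers the generating one on synthetic data", {
  sch <- sch24(1)
  p <- sim_params()
  hyp <- fixture("score_hyp", simulate_hypnogram(sch, p, seed = 21, n_epochs = 2700))
  rec <- fixture("score_rec", preprocess(simulate_eeg_emg(hyp, sch, p, seed = 22)))
  sc <- score_epochs(compute_epoch_features(rec))
  expect_gt(mean(unclass(sc) == unclass(hyp)), 0.9)
})

test_that("architecture statistics count episodes and brief awakenings", {
  sch <- sch24(1)
  # all-WAKE day: one episode, 100% of time, no brief awakenings
  allw <- new_hypnogram(rep("WAKE", 21600), "simulated")
  aw <- architecture_stats(allw, sch, n_cycles = Inf)
  for (ph in c("photophase", "scotophase")) {
    e <- aw$episodes[aw$episodes$phase == ph, ]
    expect_equal(sum(e$total_time_pct), 100, tolerance = 1e-9)
    expect_equal(e$total_time_pct[e$state == "WAKE"], 100)
  }
  expect_equal(sum(aw$episodes$episode_count), 1)
  expect_equal(aw$brief_awakenings, 0)
  # N,N,W,W,N,N: one brief awakening, one merged NREM episode
  h6 <- new_hypnogram(c("NREM", "NREM", "WAKE", "WAKE", "NREM", "NREM"),
                      "simulated")
  a6 <- architecture_stats(h6, sch, n_cycles = Inf)
  expect_equal(a6$brief_awakenings, 1)
  e6 <- a6$episodes[a6$episodes$phase == "scotophase", ]
  expect_equal(e6$episode_count[e6$state == "NREM"], 1)   # merged across BA
  expect_equal(e6$episode_count[e6$state == "WAKE"], 0)   # BA not an episode
  expect_equal(a6$brief_awakenings_per_h_nrem, 1 / (4 * 4 / 3600))
  expect_error(architecture_stats(new_hypnogram(character(0), "simulated"), sch),
               "empty")
})

test_that("long-run architecture matches the generator's stationary law", {
  sch <- sch24(10)
  p <- sim_params()
  hyp <- simulate_hypnogram(sch, p, seed = 31)
  st <- architecture_stats(hyp, sch, n_cycles = Inf)
  for (ph in c("photophase", "scotophase")) {
    tm <- if (ph == "photophase") p$trans_photo else p$trans_scoto
    pi_s <- 100 * stationary_distribution(tm)
    e <- st$episodes[st$episodes$phase == ph, ]
    obs <- e$total_time_pct[match(names(pi_s), e$state)]
    expect_lt(max(abs(obs - pi_s)), 3)
  }
})
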