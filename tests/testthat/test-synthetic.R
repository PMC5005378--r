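test_that("hypnogram simulation is deterministic and respects the chain", {
  sch <- sch24(1)
  p <- sim_params()
  h1 <- simulate_hypnogram(sch, p, seed = 7)
  h2 <- simulate_hypnogram(sch, p, seed = 7)
  expect_identical(unclass(h1), unclass(h2))
  expect_false(identical(unclass(h1), unclass(simulate_hypnogram(sch, p, seed = 8))))
  # identity transition matrix freezes the start state
  pid <- sim_params(trans_photo = diag(3), trans_scoto = diag(3))
  expect_true(all(unclass(simulate_hypnogram(sch, pid, seed = 1,
                                             n_epochs = 100)) == "WAKE"))
  # REM never follows WAKE directly
  st <- unclass(simulate_hypnogram(sch24(3), p, seed = 3))
  expect_false(any(st[-1] == "REM" & st[-length(st)] == "WAKE"))
  # WAKE -> REM probability is refused at construction
  expect_error(sim_params(trans_photo = rbind(c(0.9, 0.05, 0.05),
                                              c(0.03, 0.95, 0.02),
                                              c(0.06, 0.01, 0.93))),
               "REM")
})

test_that("state fractions match the configured stationary distributions", {
  sch <- sch24(10)
  p <- sim_params()
  hyp <- simulate_hypnogram(sch, p, seed = 11)
  fr <- state_fractions(hyp, sch)
  for (ph in c("photophase", "scotophase")) {
    tm <- if (ph == "photophase") p$trans_photo else p$trans_scoto
    pi_s <- stationary_distribution(tm)
    obs <- fr$fraction[fr$phase == ph][match(names(pi_s),
                                             fr$state[fr$phase == ph])]
    # chain mixing inflates variance vs iid sampling; absolute bound instead
    expect_lt(max(abs(obs - pi_s)), 0.03)
    expect_gt(min(obs), 0)
  }
  # nocturnal pattern: more NREM sleep in the photophase
  expect_gt(fr$fraction[fr$state == "NREM" & fr$phase == "photophase"],
            fr$fraction[fr$state == "NREM" & fr$phase == "scotophase"])
})

test_that("EEG generator is deterministic and state spectra are faithful", {
  sch <- sch24(1)
  p <- sim_params()
  hyp <- simulate_hypnogram(sch, p, seed = 1, n_epochs = 300)
  r1 <- simulate_eeg_emg(hyp, sch, p, seed = 4)
  r2 <- simulate_eeg_emg(hyp, sch, p, seed = 4)
  expect_identical(r1$eeg, r2$eeg)
  expect_identical(r1$emg, r2$emg)
  # spectral fidelity: NREM peaks in 1-4 Hz, REM in 7-9.5 Hz
  for (s in c("NREM", "REM")) {
    hs <- new_hypnogram(rep(s, 150), "simulated")
    rec <- preprocess(simulate_eeg_emg(hs, sch, p, seed = 5))
    sp <- state_spectra(rec, hs, sch)[[s]]
    pk <- sp$freqs[which.max(sp$psd)]
    if (s == "NREM") expect_true(pk >= 1 && pk <= 4)
    else expect_true(pk >= 7 && pk <= 9.5)
  }
  # hypnogram longer than schedule is a structural error
  expect_error(simulate_eeg_emg(new_hypnogram(rep("WAKE", 22000), "simulated"),
                                sch24(1), p),
               "longer than")
})

test_that("noise-free SWA envelope obeys the decay and buildup equations", {
  sch <- sch24(1)
  # isolate the SWA component: no noise, no theta/gamma in NREM
  p <- sim_params(noise_sd = 0,
                  amp_map = list(WAKE = c(swa = 0.25, theta = 1, gamma = 0.5),
                                 NREM = c(swa = 1.6, theta = 0, gamma = 0),
                                 REM  = c(swa = 0.2, theta = 1.4, gamma = 0.3)))
  hyp <- new_hypnogram(rep("NREM", 1800), "simulated")   # 2 h of NREM
  rec <- simulate_eeg_emg(hyp, sch, p, seed = 2)
  # squared SWA amplitude envelope via the analytic signal of the raw EEG
  env2 <- Mod(circsleep:::analytic_signal(rec$eeg))^2
  t_s <- (seq_along(env2) - 1) / 200
  d <- p$swa_decay; b <- p$buildup
  D <- d[["SWA0"]] * exp(-t_s / 3600 / d[["tau_h"]]) + d[["SWAinf"]]
  r <- b[["min"]] + (b[["max"]] - b[["min"]]) /
    (1 + 10^((b[["log_t50"]] - log10(t_s)) * b[["slope"]]))
  expected <- p$amp_map$NREM[["swa"]]^2 * D * r
  sel <- t_s > 120 & t_s < 7000          # clear of analytic-signal edges
  rel <- abs(env2[sel] - expected[sel]) / expected[sel]
  # envelope of an FM sine: analytic-signal magnitude tracks amplitude
  expect_lt(stats::median(rel), 0.02)
})

test_that("activity series is entrained, rectified, and reproducible", {
  sch <- make_schedule(21, 0.5, 14)
  a0 <- simulate_activity(sch, 21, amplitude = 0, mesor = 3, noise_sd = 0)
  expect_true(all(a0$distance == 3))
  act <- simulate_activity(sch, 21, seed = 6)
  expect_identical(act$distance, simulate_activity(sch, 21, seed = 6)$distance)
  expect_true(all(act$distance >= 0))
  expect_true(all(diff(act$t_min) == 1))
  # activity concentrated in scotophase
  ph <- phase_of_day(sch, act$t_min * 60)
  expect_gt(mean(act$distance[ph == "scotophase"]),
            2 * mean(act$distance[ph == "photophase"]))
  expect_error(simulate_activity(sch, -2), "entrained_period_h")
  expect_error(simulate_activity(sch, 21, amplitude = -1), "amplitude")
})
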