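# shared fixtures, built in code at test time

fix_env <- new.env()

# memoise expensive fixtures within one test run
fixture <- function(name, expr) {
  if (!exists(name, envir = fix_env)) assign(name, force(expr), envir = fix_env)
  get(name, envir = fix_env)
}

sch24 <- function(n_days = 1) make_schedule(24, 0.5, n_days)

# a sine-only recording for filter/spectra checks
sine_recording <- function(freq, dur_s = 60, amp = 1, fs = 200) {
  t <- (seq_len(dur_s * fs) - 1) / fs
  new_recording(amp * sin(2 * pi * freq * t), numeric(length(t)), fs = fs,
                schedule = sch24())
}

# frequency-modulated theta-like phase: non-degenerate for surrogate tests
fm_phase <- function(n, f0 = 8, fs = 200, jitter = 1, seed = 1) {
  with_seed <- get("with_seed", envir = asNamespace("circsleep"))
  u <- with_seed(seed, stats::runif(2, 0, 2 * pi))
  t <- (seq_len(n) - 1) / fs
  2 * pi * cumsum(f0 + jitter * sin(2 * pi * 0.11 * t + u[1])) / fs
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

# short all-WAKE recording with configurable coupling, memoised per kappa
wake_recording <- function(kappa, minutes = 10, seed = 5) {
  fixture(sprintf("wake_k%g_m%d_s%d", kappa, minutes, seed), {
    hyp <- new_hypnogram(rep("WAKE", minutes * 15), "simulated")
    preprocess(simulate_eeg_emg(hyp, sch24(),
                                sim_params(coupling_strength = kappa),
                                seed = seed))
  })
}
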