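#' Simulate an EEG/EMG recording from a hypnogram
#'
#' Synthesizes a 200-Hz two-channel recording whose spectral content follows
#' the vigilance states of `hyp`:
#' \itemize{
#'   \item a slow-wave (SWA) oscillation, frequency-modulated around 2.5 Hz,
#'     dominant in NREM, whose NREM amplitude envelope follows
#'     `sqrt(D(t_s) * r(t))` with `D(t_s) = SWA0 exp(-t_s/tau) + SWAinf` over
#'     NREM time `t_s` accumulated within the current zeitgeber cycle and
#'     `r(t)` the logistic rise over ~50 s after each wake->NREM transition,
#'     so that binned 1-3 Hz power traces the two-process envelope exactly
#'     when `noise_sd = 0`;
#'   \item a theta oscillation, frequency-modulated around 8 Hz (+/- 0.5 Hz),
#'     dominant in REM and present in WAKE;
#'   \item a gamma oscillation, frequency-modulated around 38 Hz (inside the
#'     30-45 Hz synthesis band), whose WAKE amplitude is
#'     `base * (1 + kappa * cos(theta phase))` — the ground-truth
#'     phase-amplitude coupling;
#'   \item sinusoidal zeitgeber-period modulation of theta/gamma band power
#'     (amplitude scaled by `sqrt(1 + m cos(...))`), peaking `acrophase_h`
#'     hours after lights-off;
#'   \item additive broadband Gaussian noise.
#' }
#' EMG is 20-90 Hz band-limited noise with state-dependent RMS
#' (WAKE : NREM : REM defaults 5 : 1 : 0.5).
#'
#' @param hyp a `hypnogram` (4-s epochs).
#' @param schedule the aligned `light_schedule`; must cover the hypnogram.
#' @param params a [sim_params()].
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return an object of class `recording` with elements `eeg`, `emg`,
#'   `fs = 200`, `t0 = 0`, `schedule`.
#' @export
simulate_eeg_emg <- function(hyp, schedule, params = sim_params(), seed = 1) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(schedule, "light_schedule"),
            inherits(params, "sim_params"))
  fs <- 200
  n_ep <- length(hyp)
  if (n_ep * 4 > schedule$duration_s + 1e-9)
    stop("hypnogram longer than schedule (structural mismatch)")
  n <- n_ep * 4L * fs
  st <- rep(match(unclass(hyp), vstates), each = 4L * fs)
  t <- (seq_len(n) - 1) / fs
  period_s <- if (schedule$dd) 24 * 3600 else schedule$period_h * 3600

  u <- with_seed(seed, stats::runif(6, 0, 2 * pi))  # slow-FM phase offsets

  amp_of <- function(band) vapply(params$amp_map, `[[`, numeric(1), band)[st]
  cmod <- function(band) {
    cm <- params$circadian_mod[[band]]
    if (is.null(cm) || cm[["rel_amp"]] == 0) return(1)
    sqrt(pmax(0, 1 + cm[["rel_amp"]] *
                cos(2 * pi * (t - cm[["acrophase_h"]] * 3600) / period_s)))
  }

  # theta and gamma (frequency-modulated carriers: slow incommensurate FM
  # keeps the bands narrow but non-degenerate for filter bank / surrogates);
  # components are accumulated into `eeg` and freed to bound peak memory
  phi_theta <- 2 * pi * cumsum(8 + 0.35 * sin(2 * pi * 0.047 * t + u[1]) +
                                 0.15 * sin(2 * pi * 0.013 * t + u[2])) / fs
  eeg <- amp_of("theta") * cmod("theta") * sin(phi_theta)
  kap <- ifelse(st == 1L, 1 + params$coupling_strength * cos(phi_theta), 1)
  rm(phi_theta)
  phi_gamma <- 2 * pi * cumsum(38 + 2 * sin(2 * pi * 0.061 * t + u[3])) / fs
  eeg <- eeg + amp_of("gamma") * cmod("gamma") * kap * sin(phi_gamma)
  rm(phi_gamma, kap)

  # SWA two-process envelope (NREM samples only)
  is_n <- st == 2L
  ts_cum <- cumsum(is_n) / fs                       # accumulated NREM seconds
  cyc <- floor(t / period_s)
  cyc_first <- which(!duplicated(cyc))              # first sample of each cycle
  ts_nrem <- ts_cum - ts_cum[cyc_first][cyc + 1]    # NREM time within cycle
  rm(ts_cum, cyc)
  d <- params$swa_decay
  envD <- d[["SWA0"]] * exp(-ts_nrem / (d[["tau_h"]] * 3600)) + d[["SWAinf"]]
  rm(ts_nrem)

  # logistic rise after each wake->NREM transition (epoch-run bookkeeping)
  r <- rep(1, n)
  runs <- rle(as.vector(unclass(hyp)))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  b <- params$buildup
  for (j in which(runs$values == "NREM")) {
    prev <- if (j == 1) "WAKE" else runs$values[j - 1]
    if (prev != "WAKE") next
    i0 <- (starts[j] - 1) * 4L * fs + 1
    i1 <- ends[j] * 4L * fs
    tloc <- (seq.int(i0, i1) - i0) / fs
    r[i0:i1] <- b[["min"]] + (b[["max"]] - b[["min"]]) /
      (1 + 10^((b[["log_t50"]] - log10(tloc)) * b[["slope"]]))
  }

  a_swa <- amp_of("swa")
  a_swa[is_n] <- a_swa[is_n] * sqrt(envD[is_n] * r[is_n])
  rm(envD, r, is_n)
  phi_swa <- 2 * pi * cumsum(2.5 + 0.3 * sin(2 * pi * 0.029 * t + u[4])) / fs
  rm(t)
  eeg <- eeg + a_swa * sin(phi_swa)
  rm(a_swa, phi_swa)

  with_seed(seed + 1L, {
    if (params$noise_sd > 0) eeg <- eeg + stats::rnorm(n, sd = params$noise_sd)
    emg <- stats::rnorm(n)
  })
  bp <- signal::butter(4, c(20, 90) / (fs / 2), type = "pass")
  emg <- as.numeric(signal::filter(bp, emg))
  emg <- emg / rms(emg) * params$emg_rms[vstates][st]

  new_recording(eeg, emg, fs = fs, schedule = schedule)
}

#' Recording constructor
#'
#' @param eeg,emg equal-length numeric sample vectors.
#' @param fs sampling rate in Hz.
#' @param t0 absolute start time in seconds (0 = lights-off of cycle 0).
#' @param schedule optional `light_schedule`.
#' @param preprocessed has [preprocess()] been applied?
#' @return a `recording`.
#' @export
new_recording <- function(eeg, emg, fs = 200, t0 = 0, schedule = NULL,
                          preprocessed = FALSE) {
  if (length(eeg) != length(emg)) stop("EEG and EMG must have equal length")
  structure(list(eeg = as.numeric(eeg), emg = as.numeric(emg), fs = fs,
                 t0 = t0, schedule = schedule, preprocessed = preprocessed),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Recording: %d samples at %g Hz (%.2f h)%s\n", length(x$eeg),
              x$fs, length(x$eeg) / x$fs / 3600,
              if (x$preprocessed) ", preprocessed" else ""))
  invisible(x)
}
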