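#' Filter-bank analytic-signal decomposition
#'
#' Decomposes the EEG into 1-Hz-wide bands (centers in `centers`, passband
#' center +/- 0.5 Hz) with linear-phase Hamming-windowed-sinc FIR band-pass
#' filters of the nominal 1500-point length (implemented with 1501 taps so
#' the group delay, 750 samples, is an integer), applied by FFT convolution
#' with delay compensation.  The Hilbert transform of each band gives
#' instantaneous phase (radians, in (-pi, pi]) and power (squared magnitude).
#' The first and last 750 samples are flagged edge-invalid and are excluded
#' from all downstream phase-amplitude statistics.
#'
#' For amplitude extraction in phase-amplitude coupling a wider passband is
#' required (the envelope sidebands sit at the modulating frequency away
#' from the carrier): set `halfwidth` accordingly, or use
#' [pac_comodulogram()] which applies the bandwidth rule automatically.
#'
#' @param rec a preprocessed `recording` (length > 2 x filter length).
#' @param centers band center frequencies in Hz (default 2:100).
#' @param halfwidth half passband width in Hz (default 0.5, the nominal
#'   1-Hz-wide bank).
#' @return an `analytic_bands` object: `centers`, `phase` and `power`
#'   (samples x bands matrices), `valid` (logical per sample), `fs`,
#'   `halfwidth`.
#' @export
filterbank_hilbert <- function(rec, centers = 2:100, halfwidth = 0.5) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  ntaps <- 1501L
  delay <- (ntaps - 1L) %/% 2L
  n <- length(rec$eeg)
  if (n <= 2L * ntaps)
    stop("recording shorter than twice the filter length (", 2L * ntaps, " samples)")
  nfft <- 2^ceiling(log2(n + ntaps - 1L))
  X <- stats::fft(c(rec$eeg, numeric(nfft - n)))
  m <- seq_len(ntaps) - 1L - delay            # symmetric tap index
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(ntaps) - 1) / (ntaps - 1))
  sinc <- function(f) ifelse(m == 0, 2 * f / fs, sin(2 * pi * f * m / fs) / (pi * m))
  phase <- power <- matrix(NA_real_, n, length(centers))
  for (j in seq_along(centers)) {
    h <- (sinc(centers[j] + halfwidth) - sinc(max(centers[j] - halfwidth, 0.1))) * ham
    H <- stats::fft(c(h, numeric(nfft - ntaps)))
    y <- Re(stats::fft(X * H, inverse = TRUE) / nfft)[delay + seq_len(n)]
    a <- analytic_signal(y)
    phase[, j] <- Arg(a)
    power[, j] <- Mod(a)^2
  }
  valid <- rep(TRUE, n)
  valid[c(seq_len(delay), n - delay + seq_len(delay))] <- FALSE
  structure(list(centers = centers, phase = phase, power = power,
                 valid = valid, fs = fs, t0 = rec$t0,
                 schedule = rec$schedule, halfwidth = halfwidth),
            class = "analytic_bands")
}

#' @export
print.analytic_bands <- function(x, ...) {
  cat(sprintf("Analytic band series: %d bands (%g-%g Hz), %d samples at %g Hz (%d edge-invalid)\n",
              length(x$centers), min(x$centers), max(x$centers),
              nrow(x$phase), x$fs, sum(!x$valid)))
  invisible(x)
}

#' Band power time series from analytic bands
#'
#' Mean band power (summed over the filter-bank bands inside `band`) per
#' fixed time bin, restricted to in-state, edge-valid samples.  Bins where
#' fewer than `min_frac` of the samples qualify are missing (`NA`), never
#' fabricated from out-of-state samples.
#'
#' @param bands an `analytic_bands` object.
#' @param band `c(lo, hi)` Hz; bank centers in `[lo, hi]` are summed.
#' @param state_mask logical per sample (e.g. expanded from a hypnogram via
#'   [state_sample_mask()]); `NULL` = all samples.
#' @param bin_s bin width in seconds (default 600 = 10 min).
#' @param norm `"none"`, `"median_photophase"` (divide by the median over
#'   photophase bins) or `"median_LD12"` (divide by `norm_ref`, the median
#'   computed under the LD12/12 reference condition).
#' @param norm_ref reference median for `norm = "median_LD12"`.
#' @param min_frac minimum qualifying-sample fraction per bin (default 0.5).
#' @return data.frame (t_h = bin center in hours, value, n_samples).
#' @export
band_power_series <- function(bands, band, state_mask = NULL, bin_s = 600,
                              norm = c("none", "median_photophase", "median_LD12"),
                              norm_ref = NULL, min_frac = 0.5) {
  stopifnot(inherits(bands, "analytic_bands"))
  norm <- match.arg(norm)
  sel_b <- bands$centers >= band[1] & bands$centers <= band[2]
  if (!any(sel_b)) stop("no filter-bank bands inside [", band[1], ", ", band[2], "] Hz")
  p <- rowSums(bands$power[, sel_b, drop = FALSE])
  n <- length(p)
  qual <- bands$valid & (state_mask %||% rep(TRUE, n))
  bin <- floor((seq_len(n) - 1) / (bin_s * bands$fs))
  n_bins <- max(bin) + 1L
  cnt <- tabulate(bin + 1L, n_bins)
  qcnt <- as.numeric(rowsum(as.numeric(qual), bin, reorder = TRUE))
  val <- as.numeric(rowsum(ifelse(qual, p, 0), bin, reorder = TRUE)) /
    ifelse(qcnt > 0, qcnt, NA)
  val[qcnt < min_frac * cnt] <- NA
  t_h <- (seq_len(n_bins) - 0.5) * bin_s / 3600 + bands$t0 / 3600
  out <- data.frame(t_h = t_h, value = val, n_samples = qcnt)
  apply_series_norm(out, norm, norm_ref, bands$schedule)
}

apply_series_norm <- function(out, norm, norm_ref, schedule) {
  if (norm == "median_photophase") {
    if (is.null(schedule)) stop("median_photophase normalization needs a schedule")
    ph <- phase_of_day(schedule, out$t_h * 3600)
    ref <- stats::median(out$value[ph == "photophase"], na.rm = TRUE)
    out$value <- out$value / ref
  } else if (norm == "median_LD12") {
    if (is.null(norm_ref)) stop("norm = 'median_LD12' requires norm_ref")
    out$value <- out$value / norm_ref
  }
  out
}

#' Expand a hypnogram into a per-sample state mask
#'
#' @param hyp a `hypnogram`.
#' @param state state to select.
#' @param fs sampling rate (Hz).
#' @param n total sample count (padded with `FALSE`).
#' @return logical vector of length `n`.
#' @export
state_sample_mask <- function(hyp, state, fs = 200, n = length(hyp) * 4 * fs) {
  stop_if_not_states(state)
  m <- rep(unclass(hyp) == state, each = 4 * fs)
  length(m) <- n
  m[is.na(m)] <- FALSE
  m
}

#' Band power time series from per-epoch spectra
#'
#' The periodogram-based counterpart of [band_power_series()]: per-epoch band
#' power (from the 4-s Hann/512 spectra) averaged into fixed bins over epochs
#' of one state.  This is the series used for the 10-min binned band-power
#' rhythms and the SWA analyses, where epoch resolution suffices.
#'
#' @param rec a preprocessed `recording`.
#' @param hyp aligned `hypnogram`.
#' @param band `c(lo, hi)` Hz.
#' @param state state whose epochs contribute (`NULL` = all).
#' @param bin_s bin width in seconds (multiple of 4).
#' @param norm,norm_ref,min_frac as in [band_power_series()].
#' @param schedule optional override of `rec$schedule`.
#' @return data.frame (t_h, value, n_epochs).
#' @export
epoch_band_series <- function(rec, hyp, band, state = NULL, bin_s = 600,
                              norm = c("none", "median_photophase", "median_LD12"),
                              norm_ref = NULL, min_frac = 0.5, schedule = NULL) {
  norm <- match.arg(norm)
  ev <- epoch(rec, schedule %||% rec$schedule)
  n_ep <- min(nrow(ev), length(hyp))
  p <- epoch_psd(rec, ev[seq_len(n_ep), ])
  bp <- band_sum(p, band[1], band[2])
  st <- unclass(hyp)[seq_len(n_ep)]
  qual <- if (is.null(state)) rep(TRUE, n_ep) else st == state
  bin <- floor(ev$t_start_s[seq_len(n_ep)] / bin_s)
  n_bins <- max(bin) + 1L
  cnt <- tabulate(bin + 1L, n_bins)
  qcnt <- as.numeric(rowsum(as.numeric(qual), bin, reorder = TRUE))
  val <- as.numeric(rowsum(ifelse(qual, bp, 0), bin, reorder = TRUE)) /
    ifelse(qcnt > 0, qcnt, NA)
  val[qcnt < min_frac * cnt] <- NA
  out <- data.frame(t_h = (seq_len(n_bins) - 0.5) * bin_s / 3600 + rec$t0 / 3600,
                    value = val, n_epochs = qcnt)
  apply_series_norm(out, norm, norm_ref, schedule %||% rec$schedule)
}
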