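#' Preprocess a recording
#'
#' Applies the standard EEG conditioning chain: 0.5-Hz high-pass (4th-order
#' Butterworth) and 49-51 Hz band-stop notch (2nd-order Butterworth), both
#' zero-phase (forward-backward), after removal of the channel mean.
#' Zero-phase filtering preserves the instantaneous-phase relationships the
#' phase-amplitude coupling analysis depends on.  EMG is passed through
#' unchanged (it is only used as an RMS feature).
#'
#' Filters are designed for 200 Hz; other rates are refused rather than
#' silently redesigned.
#'
#' @param rec a `recording` at 200 Hz.
#' @return the filtered `recording`, flagged `preprocessed`.
#' @export
preprocess <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs != 200)
    stop("preprocess() filters are designed for fs = 200 Hz, got ", rec$fs)
  eeg <- rec$eeg - mean(rec$eeg)
  hp <- signal::butter(4, 0.5 / (rec$fs / 2), type = "high")
  bs <- signal::butter(2, c(49, 51) / (rec$fs / 2), type = "stop")
  eeg <- signal::filtfilt(bs, signal::filtfilt(hp, eeg))
  out <- rec
  out$eeg <- eeg
  out$preprocessed <- TRUE
  out
}

#' Cut a recording into 4-s epochs
#'
#' Contiguous, non-overlapping, half-open sample ranges: epoch `k` (0-based)
#' covers samples `[k*4*fs, (k+1)*4*fs)`.  A trailing partial epoch is
#' dropped.  Each epoch carries the phase-of-day label of its first sample.
#'
#' @param rec a `recording`.
#' @param schedule optional override of `rec$schedule`.
#' @return an `epoch_view`: data.frame with `epoch` (0-based index),
#'   `start` (1-based first sample), `end` (1-based last sample), `t_start_s`
#'   and `phase`; attribute `epoch_s = 4`.
#' @export
epoch <- function(rec, schedule = NULL) {
  stopifnot(inherits(rec, "recording"))
  schedule <- schedule %||% rec$schedule
  spe <- 4L * rec$fs
  n_ep <- floor(length(rec$eeg) / spe)
  if (n_ep == 0)
    return(structure(data.frame(epoch = integer(0), start = integer(0),
                                end = integer(0), t_start_s = numeric(0),
                                phase = character(0)),
                     class = c("epoch_view", "data.frame"), epoch_s = 4))
  k <- seq_len(n_ep) - 1L
  t_start <- rec$t0 + k * 4
  phase <- if (is.null(schedule)) rep(NA_character_, n_ep) else
    phase_of_day(schedule, t_start)
  structure(data.frame(epoch = k, start = k * spe + 1L, end = (k + 1L) * spe,
                       t_start_s = t_start, phase = phase),
            class = c("epoch_view", "data.frame"), epoch_s = 4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
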