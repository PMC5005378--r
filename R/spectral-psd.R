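#' Per-epoch power spectra (Welch, 512-point, Hann)
#'
#' Each 4-s epoch (800 samples at 200 Hz) is subdivided into 512-sample
#' Hann-windowed segments with 50% overlap (two segments per epoch), the
#' one-sided periodograms are averaged, and the 0-50 Hz range is retained.
#' Frequency resolution is fs / 512 ~ 0.39 Hz.
#'
#' @param rec a `recording` (normally preprocessed).
#' @param epochs an [epoch()] view; defaults to `epoch(rec)`.
#' @return a `state_psd` list: `freqs` (Hz, length 129) and `psd`
#'   (129 x n_epochs matrix, power per Hz).
#' @export
epoch_psd <- function(rec, epochs = NULL) {
  stopifnot(inherits(rec, "recording"))
  epochs <- epochs %||% epoch(rec)
  fs <- rec$fs
  nfft <- 512L
  hop <- nfft %/% 2L
  spe <- 4L * fs
  n_seg <- (spe - nfft) %/% hop + 1L           # 2 segments for 800 samples
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nfft) / (nfft + 1)))   # Hann
  scale <- 1 / (fs * sum(w^2))
  n_keep <- nfft %/% 4L + 1L                   # bins 0 .. 50 Hz
  freqs <- (seq_len(n_keep) - 1) * fs / nfft
  n_ep <- nrow(epochs)
  psd <- matrix(0, n_keep, n_ep)
  if (n_ep == 0) return(list(freqs = freqs, psd = psd))
  chunk <- 2000L
  for (c0 in seq(1L, n_ep, by = chunk)) {
    c1 <- min(c0 + chunk - 1L, n_ep)
    idx_ep <- c0:c1
    acc <- matrix(0, n_keep, length(idx_ep))
    for (s in seq_len(n_seg)) {
      off <- (s - 1L) * hop
      idx <- outer(seq_len(nfft) + off, epochs$start[idx_ep] - 1L, `+`)
      seg <- matrix(rec$eeg[idx], nfft)
      seg <- seg * w
      X <- stats::mvfft(seg)[seq_len(n_keep), , drop = FALSE]
      p <- Mod(X)^2 * scale
      p[-1, ] <- 2 * p[-1, ]                   # one-sided (DC not doubled)
      acc <- acc + p
    }
    psd[, idx_ep] <- acc / n_seg
  }
  list(freqs = freqs, psd = psd)
}

# band power: PSD integrated over bins with frequency in [lo, hi]
band_sum <- function(psd_obj, lo, hi) {
  sel <- psd_obj$freqs >= lo & psd_obj$freqs <= hi
  df <- psd_obj$freqs[2] - psd_obj$freqs[1]
  colSums(psd_obj$psd[sel, , drop = FALSE]) * df
}
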