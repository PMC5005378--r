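#' State-specific power spectra
#'
#' Mean 4-s Hann periodogram (see [epoch_psd()]) per vigilance state, with
#' each epoch's spectrum divided by the median total (0-50 Hz) power of all
#' epochs in its zeitgeber cycle, averaged over the last `n_cycles` complete
#' cycles.  States absent from the window are flagged missing.
#'
#' @param rec a preprocessed `recording`.
#' @param hyp the aligned `hypnogram`.
#' @param schedule optional override of `rec$schedule`.
#' @param n_cycles trailing complete cycles to average (default 2).
#' @return a `state_spectra` object: list per state with `freqs`, `psd`
#'   (normalized), `n_epochs`, `missing`.
#' @export
state_spectra <- function(rec, hyp, schedule = NULL, n_cycles = 2) {
  stopifnot(inherits(rec, "recording"), inherits(hyp, "hypnogram"))
  schedule <- schedule %||% rec$schedule
  ev <- epoch(rec, schedule)
  n_ep <- min(nrow(ev), length(hyp))
  ev <- ev[seq_len(n_ep), ]
  st <- unclass(hyp)[seq_len(n_ep)]
  p <- epoch_psd(rec, ev)
  total <- band_sum(p, 0, 50)
  cyc <- if (is.null(schedule)) rep(0L, n_ep) else
    cycle_index(schedule, ev$t_start_s)
  med <- tapply(total, cyc, stats::median)
  norm <- as.numeric(med[as.character(cyc)])
  psd_n <- sweep(p$psd, 2, norm, "/")

  keep <- rep(TRUE, n_ep)
  if (!is.null(schedule)) {
    win <- last_cycles_window(schedule, n_ep * 4, n_cycles)
    keep <- ev$t_start_s >= win[1] & ev$t_start_s < win[2]
  }
  out <- lapply(vstates, function(s) {
    sel <- keep & st == s
    if (!any(sel)) return(list(freqs = p$freqs, psd = rep(NA_real_, length(p$freqs)),
                               n_epochs = 0L, missing = TRUE))
    list(freqs = p$freqs, psd = rowMeans(psd_n[, sel, drop = FALSE]),
         n_epochs = sum(sel), missing = FALSE)
  })
  names(out) <- vstates
  structure(out, class = "state_spectra")
}

#' @export
print.state_spectra <- function(x, ...) {
  cat("State spectra (0-50 Hz, fs/512 resolution):\n")
  for (s in names(x)) cat(sprintf("  %s: %s (%d epochs)\n", s,
    if (x[[s]]$missing) "missing" else "present", x[[s]]$n_epochs))
  invisible(x)
}

#' Band power on short fixed bins (single zero-padded FFT per bin)
#'
#' Splits the EEG into contiguous `bin_s`-second segments, Hann-windows each,
#' zero-pads to 512 points and sums the periodogram over `band`.  Used for
#' the 2-s bins of the SWA-buildup analysis.
#'
#' @param rec a preprocessed `recording`.
#' @param band `c(lo, hi)` in Hz.
#' @param bin_s bin width in seconds (`bin_s * fs <= 512`).
#' @return numeric vector of band power per bin.
#' @export
stft_band_power <- function(rec, band, bin_s = 2) {
  fs <- rec$fs
  nb <- bin_s * fs
  if (nb > 512) stop("bin too long for the 512-point FFT")
  n_bins <- floor(length(rec$eeg) / nb)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nb) / (nb + 1)))
  seg <- matrix(rec$eeg[seq_len(n_bins * nb)], nb)
  seg <- seg * w
  segp <- rbind(seg, matrix(0, 512 - nb, n_bins))
  X <- stats::mvfft(segp)
  freqs <- (0:256) * fs / 512
  sel <- freqs >= band[1] & freqs <= band[2]
  p <- Mod(X[seq_len(257), , drop = FALSE])^2 / (fs * sum(w^2))
  p[-1, ] <- 2 * p[-1, ]
  colSums(p[sel, , drop = FALSE])
}

#' Compare paired spectra between conditions (cluster permutation)
#'
#' Per-frequency paired t-tests between two conditions; contiguous runs of
#' frequencies exceeding the `thresh_p` threshold form clusters whose summed
#' t (cluster mass) is tested against the max-mass distribution from
#' sign-flip permutations of the subject difference spectra.
#'
#' @param cond_a,cond_b subjects x frequencies matrices (same subjects in the
#'   same row order; >= 3 rows).
#' @param freqs frequency grid (columns).
#' @param n_perm,thresh_p,cluster_p permutation count and thresholds
#'   (defaults 500 / 0.01 / 0.05).
#' @param seed RNG seed for the permutations.
#' @return a `cluster_test` (see [cluster_perm_test()]) with `freqs` attached;
#'   `clusters` carry frequency bounds.
#' @export
compare_spectra <- function(cond_a, cond_b, freqs = NULL, n_perm = 500,
                            thresh_p = 0.01, cluster_p = 0.05, seed = 1) {
  if (!all(dim(cond_a) == dim(cond_b)))
    stop("conditions must be paired: equal subjects x frequency matrices")
  res <- cluster_perm_test(cond_b - cond_a, dims = c(1L, ncol(cond_a)),
                           n_perm = n_perm, thresh_p = thresh_p,
                           cluster_p = cluster_p, seed = seed)
  res$freqs <- freqs
  if (!is.null(freqs)) for (i in seq_along(res$clusters)) {
    res$clusters[[i]]$freq_lo <- min(freqs[res$clusters[[i]]$cells])
    res$clusters[[i]]$freq_hi <- max(freqs[res$clusters[[i]]$cells])
  }
  res
}
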