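#' Phase-amplitude coupling modulation index
#'
#' Mean-vector-length modulation index
#' `mi = | sum_t a_t exp(i phi_t) | / n`: the modulus of the amplitude-
#' weighted mean phase vector.  Zero when amplitude is independent of phase
#' over whole cycles; equal to `mean(a)` when the phase is constant.
#'
#' @param phase phase angles in radians.
#' @param amp non-negative amplitude/power values, same length.
#' @return scalar `mi >= 0`.
#' @export
pac_mi <- function(phase, amp) {
  if (length(phase) != length(amp)) stop("phase and amp must have equal length")
  if (length(phase) < 1) stop("need at least one sample")
  Mod(sum(amp * exp(1i * phase))) / length(phase)
}

# mi for every cyclic shift k = 0..n-1 of amp relative to phase, via one FFT
# cross-correlation; element 1 (k = 0) is the observed mi.  A cut-and-swap
# surrogate at cut point c equals the cyclic shift k = c.
all_shift_mi <- function(phase, amp) {
  n <- length(phase)
  q <- exp(1i * phase)
  s <- stats::fft(stats::fft(amp) * Conj(stats::fft(q)), inverse = TRUE) / n
  Mod(s) / n
}

#' Surrogate-normalized coupling (PACz)
#'
#' z-scores the observed modulation index against surrogates built by
#' cutting the power series at a random point and swapping the two halves
#' (equivalently: a random cyclic shift), which misaligns amplitude and
#' phase while preserving both autocorrelation structures.
#'
#' @param phase,amp as in [pac_mi()].
#' @param n_surrogates number of surrogates (>= 50; default 200).
#' @param seed RNG seed for the cut points.
#' @return scalar `pacz = (mi_obs - mean(mi_surr)) / sd(mi_surr)`; `NA` with
#'   a warning when the surrogate distribution is degenerate (constant
#'   amplitude).
#' @export
pacz <- function(phase, amp, n_surrogates = 200, seed = 1) {
  if (length(phase) != length(amp)) stop("phase and amp must have equal length")
  if (n_surrogates < 50) stop("n_surrogates must be >= 50")
  n <- length(phase)
  if (n < 3) stop("series too short")
  mis <- all_shift_mi(phase, amp)
  ks <- with_seed(seed, {
    pool <- seq_len(n - 1)                    # cut points 1..n-1
    if (length(pool) > n_surrogates) sample(pool, n_surrogates) else pool
  })
  mu <- mean(mis[ks + 1]); sdv <- stats::sd(mis[ks + 1])
  if (!is.finite(sdv) || sdv <= 1e-10 * max(mu, mis[1], 1e-300)) {
    warning("degenerate surrogate distribution (constant amplitude?); PACz undefined")
    return(NA_real_)
  }
  (mis[1] - mu) / sdv
}

#' Comodulogram: median PACz over 1-min bins
#'
#' For every (phase band, amplitude band) pair of the grid, PACz is computed
#' in 1-min bins restricted to edge-valid, in-state samples (bins with less
#' than `min_frac` in-state samples are dropped), and the median over bins is
#' taken separately for photophase and scotophase (bins assigned to the phase
#' of day at their start).
#'
#' @param bands an `analytic_bands` covering both the phase and amplitude
#'   frequency ranges.
#' @param hyp aligned `hypnogram`.
#' @param schedule `light_schedule` (defaults to the one in `bands`).
#' @param state vigilance state to analyse.
#' @param phase_centers,amp_centers frequency grids (Hz); defaults 2-20 and
#'   2-50 in 2-Hz steps.  Each must be a subset of `bands$centers`.
#' @param bin_s bin width in seconds (default 60).
#' @param n_surrogates,seed passed to the surrogate machinery.
#' @param min_frac minimum in-state fraction per bin (default 0.5).
#' @param n_cycles trailing complete zeitgeber cycles to use (default 2;
#'   `Inf` = all).
#' @param amp_bands source of the amplitude (power) series: `NULL` uses
#'   `bands` itself (the literal narrow bank — note that a 1-Hz-wide
#'   amplitude filter removes envelope modulation faster than ~0.5 Hz);
#'   a single `analytic_bands`; or a list of `analytic_bands` named by phase
#'   center, one per comodulogram row (what [pac_comodulogram()] builds).
#' @return a `comodulogram`: list with `pacz` (named list
#'   photophase/scotophase of phase x amp matrices of median PACz), `n_bins`
#'   (matching bin counts), grids and metadata.  All-missing matrices (with a
#'   warning) when no bin qualifies.
#' @export
comodulogram <- function(bands, hyp, schedule = NULL, state = "WAKE",
                         phase_centers = seq(2, 20, by = 2),
                         amp_centers = seq(2, 50, by = 2),
                         bin_s = 60, n_surrogates = 200, seed = 1,
                         min_frac = 0.5, n_cycles = Inf, amp_bands = NULL) {
  stopifnot(inherits(bands, "analytic_bands"), inherits(hyp, "hypnogram"))
  schedule <- schedule %||% bands$schedule
  if (!all(phase_centers %in% bands$centers))
    stop("requested phase frequencies missing from the filter bank")
  amp_for_row <- if (is.null(amp_bands)) {
    function(fp) bands
  } else if (inherits(amp_bands, "analytic_bands")) {
    function(fp) amp_bands
  } else {
    function(fp) amp_bands[[as.character(fp)]]
  }
  for (fp in phase_centers)
    if (!all(amp_centers %in% amp_for_row(fp)$centers))
      stop("requested amplitude frequencies missing from the amplitude bank")
  n <- nrow(bands$phase)
  mask <- state_sample_mask(hyp, state, bands$fs, n) & bands$valid
  t_s <- bands$t0 + (seq_len(n) - 1) / bands$fs
  if (is.finite(n_cycles) && !is.null(schedule)) {
    win <- last_cycles_window(schedule, max(t_s) + 1 / bands$fs, n_cycles)
    mask <- mask & t_s >= win[1] & t_s < win[2]
  }
  bin <- floor(t_s / bin_s)
  ubins <- sort(unique(bin))
  frac <- vapply(ubins, function(b) mean(mask[bin == b]), numeric(1))
  use <- ubins[frac >= min_frac]
  day_phase <- if (is.null(schedule)) rep("scotophase", length(use)) else
    phase_of_day(schedule, use * bin_s)

  pi_idx <- match(phase_centers, bands$centers)
  dims <- c(length(phase_centers), length(amp_centers))
  vals <- array(NA_real_, c(dims, length(use)))
  for (k in seq_along(use)) {
    sel <- which(bin == use[k] & mask)
    bin_seed <- seed + 977L * k
    for (ii in seq_along(pi_idx)) {
      ab <- amp_for_row(phase_centers[ii])
      ai_idx <- match(amp_centers, ab$centers)
      ph <- bands$phase[sel, pi_idx[ii]]
      for (jj in seq_along(ai_idx)) {
        vals[ii, jj, k] <- suppressWarnings(
          pacz(ph, ab$power[sel, ai_idx[jj]], n_surrogates,
               seed = bin_seed + ii * 131L + jj))
      }
    }
  }
  if (length(use) == 0)
    warning("no qualifying ", state, " bins; comodulogram is all-missing")
  med_of <- function(which_bins) {
    if (!any(which_bins))
      return(list(pacz = matrix(NA_real_, dims[1], dims[2]), n = 0L))
    list(pacz = apply(vals[, , which_bins, drop = FALSE], c(1, 2),
                      stats::median, na.rm = TRUE),
         n = sum(which_bins))
  }
  photo <- med_of(day_phase == "photophase")
  scoto <- med_of(day_phase == "scotophase")
  dn <- list(paste0(phase_centers), paste0(amp_centers))
  dimnames(photo$pacz) <- dimnames(scoto$pacz) <- dn
  structure(list(pacz = list(photophase = photo$pacz, scotophase = scoto$pacz),
                 n_bins = c(photophase = photo$n, scotophase = scoto$n),
                 phase_centers = phase_centers, amp_centers = amp_centers,
                 state = state, bin_s = bin_s, n_surrogates = n_surrogates),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("Comodulogram (%s): phase %g-%g Hz x amp %g-%g Hz; bins photo %d / scoto %d\n",
              x$state, min(x$phase_centers), max(x$phase_centers),
              min(x$amp_centers), max(x$amp_centers),
              x$n_bins[["photophase"]], x$n_bins[["scotophase"]]))
  invisible(x)
}

#' Comodulogram from a recording (with the amplitude-bandwidth rule)
#'
#' Convenience wrapper around [filterbank_hilbert()] and [comodulogram()]:
#' phase series come from the nominal 1-Hz-wide bank; the amplitude series
#' for each phase-frequency row come from a bank whose half-width is
#' `amp_halfwidth(phase_f)` (default `phase_f + 1` Hz), wide enough to pass
#' envelope modulation at the phase frequency — without this no
#' phase-amplitude coupling is detectable in principle.
#'
#' @param rec a preprocessed `recording`.
#' @param hyp aligned `hypnogram`.
#' @param amp_halfwidth function of the phase frequency giving the amplitude
#'   filter half-width in Hz.
#' @inheritParams comodulogram
#' @return a `comodulogram`.
#' @export
pac_comodulogram <- function(rec, hyp, schedule = NULL, state = "WAKE",
                             phase_centers = seq(2, 20, by = 2),
                             amp_centers = seq(2, 50, by = 2),
                             amp_halfwidth = function(fp) fp + 1,
                             bin_s = 60, n_surrogates = 200, seed = 1,
                             min_frac = 0.5, n_cycles = Inf) {
  phase_bank <- filterbank_hilbert(rec, centers = phase_centers)
  hw <- vapply(phase_centers, amp_halfwidth, numeric(1))
  banks_by_hw <- lapply(unique(hw), function(h)
    filterbank_hilbert(rec, centers = amp_centers, halfwidth = h))
  names(banks_by_hw) <- as.character(unique(hw))
  amp_bands <- lapply(as.character(hw), function(h) banks_by_hw[[h]])
  names(amp_bands) <- as.character(phase_centers)
  comodulogram(phase_bank, hyp, schedule %||% rec$schedule, state = state,
               phase_centers = phase_centers, amp_centers = amp_centers,
               bin_s = bin_s, n_surrogates = n_surrogates, seed = seed,
               min_frac = min_frac, n_cycles = n_cycles,
               amp_bands = amp_bands)
}

#' Compare paired comodulograms between conditions
#'
#' Cell-wise paired t-tests on per-subject median-PACz matrices, thresholded
#' at `thresh_p`, 4-connected clusters, and sign-flip max-mass permutation
#' correction — the 2-D application of [cluster_perm_test()].
#'
#' @param mats_a,mats_b lists (one element per subject, same order) of
#'   phase x amp PACz matrices for the two conditions.
#' @param n_perm,thresh_p,cluster_p,seed see [cluster_perm_test()].
#' @return a `cluster_test`; cluster cells index the phase x amp grid in
#'   column-major order.
#' @export
cluster_compare <- function(mats_a, mats_b, n_perm = 500, thresh_p = 0.01,
                            cluster_p = 0.05, seed = 1) {
  if (length(mats_a) != length(mats_b)) stop("conditions must be paired")
  dims <- dim(mats_a[[1]])
  if (!all(vapply(c(mats_a, mats_b), function(m) all(dim(m) == dims), TRUE)))
    stop("all matrices must share the same grid")
  diffs <- t(vapply(seq_along(mats_a),
                    function(i) as.numeric(mats_b[[i]] - mats_a[[i]]),
                    numeric(prod(dims))))
  cluster_perm_test(diffs, dims = dims, n_perm = n_perm, thresh_p = thresh_p,
                    cluster_p = cluster_p, seed = seed)
}
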