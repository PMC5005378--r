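#' Per-epoch scoring features
#'
#' Band powers from the 4-s Hann periodogram (see [epoch_psd()]) and EMG RMS:
#' slow-wave activity (SWA, 1-4 Hz), theta (7-9.5 Hz), total (0-50 Hz) power,
#' and the EMG root-mean-square over the epoch.
#'
#' @param rec a preprocessed `recording`.
#' @param epochs an [epoch()] view; defaults to `epoch(rec)`.
#' @return data.frame (epoch, swa_power, theta_power, total_power, emg_rms).
#' @export
compute_epoch_features <- function(rec, epochs = NULL) {
  stopifnot(inherits(rec, "recording"))
  epochs <- epochs %||% epoch(rec)
  p <- epoch_psd(rec, epochs)
  emg_rms <- vapply(seq_len(nrow(epochs)), function(i)
    rms(rec$emg[epochs$start[i]:epochs$end[i]]), numeric(1))
  data.frame(epoch = epochs$epoch,
             swa_power = band_sum(p, 1, 4),
             theta_power = band_sum(p, 7, 9.5),
             total_power = band_sum(p, 0, 50),
             emg_rms = emg_rms)
}

# deterministic 1-D 2-means (Lloyd from the extremes); returns the midpoint
# of the two centers
split_midpoint <- function(x) {
  c1 <- min(x); c2 <- max(x)
  if (c2 - c1 < 1e-12) return(c1)
  for (i in 1:100) {
    a <- abs(x - c1) <= abs(x - c2)
    n1 <- mean(x[a]); n2 <- mean(x[!a])
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) break
    c1 <- n1; c2 <- n2
  }
  (c1 + c2) / 2
}

#' Default scoring thresholds
#'
#' The EMG threshold is auto-calibrated per recording as the midpoint of a
#' two-component split of log EMG RMS (robust to amplitude scale); the SWA
#' ratio and theta/delta thresholds are fixed configuration.
#'
#' @param features output of [compute_epoch_features()].
#' @param swa_ratio_threshold NREM rule: `swa/total >=` this.
#' @param theta_delta_threshold REM rule: `theta/swa >= ` this.
#' @return list of thresholds.
#' @export
default_thresholds <- function(features, swa_ratio_threshold = 0.45,
                               theta_delta_threshold = 1.5) {
  pos <- features$emg_rms[features$emg_rms > 0]
  emg_threshold <- if (length(pos)) exp(split_midpoint(log(pos))) else 0
  list(emg_threshold = emg_threshold,
       swa_ratio_threshold = swa_ratio_threshold,
       theta_delta_threshold = theta_delta_threshold)
}

#' Rule-based vigilance-state scoring
#'
#' Three-rule threshold classifier with the classical rodent state
#' definitions: WAKE when EMG RMS is high; otherwise NREM when the EEG is
#' dominated by slow-wave activity (`swa/total >= swa_ratio_threshold`);
#' otherwise REM when theta dominates delta (`theta/swa >=
#' theta_delta_threshold`); otherwise NREM.  REM is accepted only when the
#' preceding non-brief state is NREM; other REM runs are relabelled WAKE.
#' Epochs with all-zero features are labelled WAKE and flagged.
#'
#' @param features output of [compute_epoch_features()].
#' @param thresholds list as returned by [default_thresholds()] (the default).
#' @return a `hypnogram` (provenance `"scored"`).
#' @export
score_epochs <- function(features, thresholds = NULL) {
  thresholds <- thresholds %||% default_thresholds(features)
  zero <- features$total_power == 0 & features$emg_rms == 0
  if (any(zero)) warning(sum(zero), " all-zero epoch(s) labelled WAKE")
  wake <- features$emg_rms >= thresholds$emg_threshold
  swa_ratio <- ifelse(features$total_power > 0,
                      features$swa_power / features$total_power, 0)
  td_ratio <- ifelse(features$swa_power > 0,
                     features$theta_power / features$swa_power, 0)
  st <- ifelse(wake, "WAKE",
        ifelse(swa_ratio >= thresholds$swa_ratio_threshold, "NREM",
        ifelse(td_ratio >= thresholds$theta_delta_threshold, "REM", "NREM")))
  st[zero] <- "WAKE"
  st <- enforce_rem_context(st)
  new_hypnogram(st, provenance = "scored", flags = zero)
}

# REM only after NREM: walk runs; a REM run whose nearest preceding
# non-brief (> 4 epochs) run is not NREM becomes WAKE
enforce_rem_context <- function(st, brief_max = 4L) {
  runs <- rle(st)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in which(runs$values == "REM")) {
    ok <- FALSE
    for (k in rev(seq_len(j - 1))) {
      if (runs$lengths[k] <= brief_max && runs$values[k] == "WAKE") next
      ok <- runs$values[k] %in% c("NREM", "REM")
      break
    }
    if (!ok) {
      st[starts[j]:ends[j]] <- "WAKE"
      runs$values[j] <- "WAKE"
    }
  }
  st
}

#' Sleep-architecture statistics
#'
#' Episodes are maximal runs of one state.  A brief awakening is a WAKE run
#' of at most 4 epochs (16 s) flanked by NREM on both sides; brief awakenings
#' are counted but do not split NREM episodes (nor enter the WAKE episode
#' statistics).  Statistics are computed per phase of day over the last
#' `n_cycles` complete zeitgeber cycles (episodes assigned to the phase of
#' their first epoch).
#'
#' @param hyp a `hypnogram` aligned to `schedule` (epoch 0 at time 0).
#' @param schedule a `light_schedule`.
#' @param n_cycles number of trailing complete cycles to analyse (default 2,
#'   the usual "last 2 days of the stage" restriction); `Inf` = all data.
#' @param brief_max maximum brief-awakening length in epochs (default 4).
#' @return list with `episodes` (per state x phase: episode_count,
#'   total_time_pct, mean_episode_length_s), `brief_awakenings_per_h_nrem`,
#'   `brief_awakenings_per_pct_nrem` and `n_epochs_used`.
#' @export
architecture_stats <- function(hyp, schedule, n_cycles = 2, brief_max = 4L) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(schedule, "light_schedule"))
  if (length(hyp) == 0) stop("empty hypnogram")
  t_ep <- (seq_along(hyp) - 1) * 4
  if (is.finite(n_cycles)) {
    win <- last_cycles_window(schedule, length(hyp) * 4, n_cycles)
    keep <- t_ep >= win[1] & t_ep < win[2]
  } else keep <- rep(TRUE, length(hyp))
  st <- unclass(hyp)[keep]
  t_ep <- t_ep[keep]
  phase <- phase_of_day(schedule, t_ep)

  runs <- rle(st)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  nr <- length(runs$values)
  brief <- runs$values == "WAKE" & runs$lengths <= brief_max &
    c(FALSE, runs$values[-nr] == "NREM") &
    c(runs$values[-1] == "NREM", FALSE)

  # merge NREM episodes across brief awakenings for episode statistics
  merged_state <- runs$values
  merged_state[brief] <- "NREM"
  m <- rle(merged_state)
  m_ends <- cumsum(m$lengths)                 # in run units
  m_starts <- m_ends - m$lengths + 1L
  ep_state <- m$values
  ep_len_epochs <- vapply(seq_along(m$values), function(j)
    sum(runs$lengths[m_starts[j]:m_ends[j]]), numeric(1))
  ep_phase <- phase[starts[m_starts]]

  phases <- unique(phase)
  out <- expand.grid(state = vstates, phase = phases,
                     stringsAsFactors = FALSE)
  out$episode_count <- mapply(function(s, p)
    sum(ep_state == s & ep_phase == p), out$state, out$phase)
  out$total_time_pct <- mapply(function(s, p)
    100 * sum(st == s & phase == p) / max(1, sum(phase == p)),
    out$state, out$phase)
  out$mean_episode_length_s <- mapply(function(s, p) {
    sel <- ep_state == s & ep_phase == p
    if (!any(sel)) NA_real_ else mean(ep_len_epochs[sel]) * 4
  }, out$state, out$phase)

  nrem_h <- sum(st == "NREM") * 4 / 3600
  nrem_pct <- 100 * sum(st == "NREM") / length(st)
  list(episodes = out,
       brief_awakenings = sum(brief),
       brief_awakenings_per_h_nrem = if (nrem_h > 0) sum(brief) / nrem_h else NA_real_,
       brief_awakenings_per_pct_nrem = if (nrem_pct > 0) sum(brief) / nrem_pct else NA_real_,
       n_epochs_used = length(st))
}
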