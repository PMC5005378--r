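#' Pipeline run configuration
#'
#' Assembles the configuration for [run_pipeline()]: the sequence of
#' light-dark stages (each simulated with its own schedule), the generator
#' parameters, analysis toggles and statistical thresholds.  Day counts
#' default to a desk-scale 3 days per LD stage (2 under DD); the full
#' experiment scale (14/7/14/14) is a configuration choice.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; each stage derives its own sub-seed.
#' @param stages list of stage descriptors: `name`, `period_h`, `dd`,
#'   `n_days`, optional `circadian_rel_amp` (overrides the generator's
#'   theta/gamma modulation depth for that stage, e.g. 0 to silence the EEG
#'   rhythm while activity stays entrained) and `activity_period_h`.
#' @param params a [sim_params()] object.
#' @param eeg_cycles trailing zeitgeber cycles per stage to synthesize EEG
#'   for (0 disables all EEG analyses; analyses use the last 2 cycles of a
#'   stage, so 2 is the default).
#' @param analyses logical toggles: `scoring`, `spectra`, `rhythm`,
#'   `homeostasis`, `pac`.
#' @param thresholds `thresh_p`, `cluster_p`, `alpha_periodogram`.
#' @param write_recording write the (large) EEG/EMG CSV per stage?
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("circsleep_run_"), seed = 1,
                       stages = list(
                         list(name = "LD12", period_h = 24, dd = FALSE, n_days = 3),
                         list(name = "LD11", period_h = 22, dd = FALSE, n_days = 3),
                         list(name = "DD", period_h = NA, dd = TRUE, n_days = 2),
                         list(name = "LD105", period_h = 21, dd = FALSE, n_days = 3)),
                       params = sim_params(), eeg_cycles = 2,
                       analyses = list(scoring = TRUE, spectra = TRUE,
                                       rhythm = TRUE, homeostasis = TRUE,
                                       pac = FALSE),
                       thresholds = list(thresh_p = 0.01, cluster_p = 0.05,
                                         alpha_periodogram = 0.01),
                       write_recording = FALSE) {
  structure(list(out_dir = out_dir, seed = seed, stages = stages,
                 params = params, eeg_cycles = eeg_cycles,
                 analyses = analyses, thresholds = thresholds,
                 write_recording = write_recording),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' For each configured stage: simulate the schedule, hypnogram and activity;
#' run the chi-square periodogram and activity cosinor; synthesize EEG/EMG
#' for the trailing `eeg_cycles` cycles; preprocess, score (reporting
#' agreement with the generating hypnogram), compute state spectra,
#' theta/gamma band-power rhythms with cosinor fits, the SWA decay and
#' buildup fits, and (optionally) the wake comodulogram.  Across stages,
#' decay fits are compared to the first stage with the extra-sum-of-squares
#' F test.  Every output file is listed, with its MD5, in `manifest.json`;
#' re-running with the same config and seed reproduces the manifest
#' byte-identically.  A stage failure aborts with a stage-attributed error;
#' outputs of completed stages are retained and the manifest marks the
#' failure.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = serialize_config(config), stages = list(),
                   comparisons = list(), status = "running")
  decay_data <- list()
  theta_fits <- list()
  for (si in seq_along(config$stages)) {
    sg <- config$stages[[si]]
    res <- tryCatch(
      run_stage(sg, config, stage_seed = config$seed + 1000L * si),
      error = function(e) e)
    gc(FALSE)                                # compact between stages
    if (inherits(res, "error")) {
      manifest$status <- paste0("failed at stage ", sg$name)
      write_manifest(manifest, config$out_dir)
      stop("pipeline stage '", sg$name, "' failed: ", conditionMessage(res))
    }
    manifest$stages[[sg$name]] <- res$manifest
    if (!is.null(res$decay_data)) decay_data[[sg$name]] <- res$decay_data
    if (!is.null(res$theta_fit)) theta_fits[[sg$name]] <- res$theta_fit
  }
  if (length(decay_data) >= 2) {
    base <- names(decay_data)[1]
    for (nm in names(decay_data)[-1]) {
      ft <- compare_fits_ftest(decay_data[[base]], decay_data[[nm]],
                               model = "decay", free = c("SWA0", "SWAinf"))
      manifest$comparisons[[paste0("decay_", base, "_vs_", nm)]] <-
        list(F = ft$F, df_num = ft$df_num, df_den = ft$df_den, p = ft$p)
    }
  }
  if (length(theta_fits)) {
    manifest$comparisons$theta_cosinor_p <-
      lapply(theta_fits, function(f) f$p_zero_amplitude)
  }
  manifest$status <- "complete"
  write_manifest(manifest, config$out_dir)
  invisible(manifest)
}

serialize_config <- function(config) {
  list(seed = config$seed, eeg_cycles = config$eeg_cycles,
       analyses = config$analyses, thresholds = config$thresholds,
       stages = config$stages,
       params = list(coupling_strength = config$params$coupling_strength,
                     noise_sd = config$params$noise_sd,
                     swa_decay = as.list(config$params$swa_decay),
                     buildup = as.list(config$params$buildup),
                     circadian_mod = lapply(config$params$circadian_mod, as.list)))
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null", na = "null")
}

file_entry <- function(path) {
  list(file = basename(path), md5 = unname(tools::md5sum(path)))
}

run_stage <- function(sg, config, stage_seed) {
  dir <- file.path(config$out_dir, sg$name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params
  if (!is.null(sg$circadian_rel_amp)) {
    for (b in names(params$circadian_mod))
      params$circadian_mod[[b]]["rel_amp"] <- sg$circadian_rel_amp
  }
  schedule <- if (isTRUE(sg$dd)) make_schedule(dd = TRUE, n_days = sg$n_days)
    else make_schedule(sg$period_h, 0.5, sg$n_days)
  m <- list(parameters = list(seed = stage_seed, period_h = sg$period_h,
                              dd = isTRUE(sg$dd), n_days = sg$n_days))
  out <- list()

  hyp <- simulate_hypnogram(schedule, params, seed = stage_seed)
  f_hyp <- file.path(dir, "hypnogram_truth.csv")
  write_hypnogram(hyp, f_hyp)
  m$files <- list(file_entry(f_hyp))
  arch <- architecture_stats(hyp, schedule)
  f_arch <- file.path(dir, "architecture.json")
  jsonlite::write_json(list(episodes = arch$episodes,
                            brief_awakenings_per_h_nrem = arch$brief_awakenings_per_h_nrem,
                            brief_awakenings_per_pct_nrem = arch$brief_awakenings_per_pct_nrem),
                       f_arch, auto_unbox = TRUE, digits = 10, na = "null")
  m$files <- c(m$files, list(file_entry(f_arch)))

  if (isTRUE(config$analyses$rhythm)) {
    act_period <- sg$activity_period_h %||%
      (if (isTRUE(sg$dd)) 23.7 else sg$period_h)
    act <- simulate_activity(schedule, act_period, seed = stage_seed + 1L)
    f_act <- file.path(dir, "activity.csv")
    write_activity(act, f_act)
    m$files <- c(m$files, list(file_entry(f_act)))
    if (length(act$distance) >= 2 * 32 * 60) {   # span supports the 16-32 h grid
      pg <- chi2_periodogram(act$distance, bin_min = 1,
                             alpha = config$thresholds$alpha_periodogram)
      f_pg <- file.path(dir, "periodogram.csv")
      utils::write.csv(as.data.frame(pg), f_pg, row.names = FALSE)
      m$files <- c(m$files, list(file_entry(f_pg)))
      m$results$activity_peak_period_h <- attr(pg, "peak_period_h")
    }
    cf_act <- cosinor_fit(act$t_min / 60, act$distance, period_h = act_period)
    f_cos <- file.path(dir, "cosinor_activity.json")
    jsonlite::write_json(cosinor_json(cf_act), f_cos, auto_unbox = TRUE,
                         digits = 10)
    m$files <- c(m$files, list(file_entry(f_cos)))
    m$results$activity_cosinor_p <- cf_act$p_zero_amplitude
  }

  res <- list()
  if (config$eeg_cycles > 0) {
    period_s <- if (schedule$dd) 24 * 3600 else schedule$period_h * 3600
    n_cyc <- min(config$eeg_cycles, floor(schedule$duration_s / period_s))
    n_ep <- floor(n_cyc * period_s / 4)
    sub_hyp <- simulate_hypnogram(schedule, params, seed = stage_seed + 2L,
                                  n_epochs = n_ep)
    rec <- simulate_eeg_emg(sub_hyp, schedule, params, seed = stage_seed + 3L)
    if (isTRUE(config$write_recording)) {
      f_rec <- file.path(dir, "recording.csv")
      write_recording(rec, f_rec)
      m$files <- c(m$files, list(file_entry(f_rec)))
    }
    rec <- preprocess(rec)

    if (isTRUE(config$analyses$scoring)) {
      feats <- compute_epoch_features(rec)
      scored <- score_epochs(feats)
      f_sc <- file.path(dir, "hypnogram_scored.csv")
      write_hypnogram(scored, f_sc)
      m$files <- c(m$files, list(file_entry(f_sc)))
      m$results$scoring_agreement <-
        mean(unclass(scored) == unclass(sub_hyp)[seq_along(scored)])
    }
    if (isTRUE(config$analyses$spectra)) {
      sp <- state_spectra(rec, sub_hyp, schedule)
      f_sp <- file.path(dir, "state_spectra.csv")
      sp_df <- do.call(rbind, lapply(names(sp), function(s)
        if (!sp[[s]]$missing)
          data.frame(state = s, freq = sp[[s]]$freqs, psd = sp[[s]]$psd)))
      utils::write.csv(sp_df, f_sp, row.names = FALSE)
      m$files <- c(m$files, list(file_entry(f_sp)))
    }
    if (isTRUE(config$analyses$rhythm)) {
      th <- epoch_band_series(rec, sub_hyp, c(7, 9.5), state = "WAKE",
                              bin_s = 600, schedule = schedule)
      per_h <- if (schedule$dd) 24 else schedule$period_h
      theta_fit <- cosinor_fit(th$t_h, th$value, period_h = per_h)
      f_th <- file.path(dir, "cosinor_theta.json")
      jsonlite::write_json(cosinor_json(theta_fit), f_th, auto_unbox = TRUE,
                           digits = 10)
      m$files <- c(m$files, list(file_entry(f_th)))
      m$results$theta_cosinor_p <- theta_fit$p_zero_amplitude
      res$theta_fit <- theta_fit
    }
    if (isTRUE(config$analyses$homeostasis)) {
      sw <- swa_nrem_series(rec, sub_hyp, schedule)
      dfit <- tryCatch(swa_decay_fit(sw$t_h, sw$swa), error = function(e) NULL)
      if (!is.null(dfit)) {
        f_sw <- file.path(dir, "swa_decay.json")
        jsonlite::write_json(list(SWA0 = dfit$SWA0, tau_h = dfit$tau_h,
                                  SWAinf = dfit$SWAinf, rss = dfit$rss,
                                  df = dfit$df, p_model = dfit$p_model,
                                  flags = dfit$flags),
                             f_sw, auto_unbox = TRUE, digits = 10)
        m$files <- c(m$files, list(file_entry(f_sw)))
        m$results$swa_tau_h <- dfit$tau_h
        res$decay_data <- list(t = sw$t_h, y = sw$swa)
      }
      bts <- tryCatch(transition_swa(rec, sub_hyp), error = function(e) NULL)
      if (!is.null(bts)) {
        bfit <- buildup_fit(bts$mean$t_s, bts$mean$y)
        f_bu <- file.path(dir, "swa_buildup.json")
        jsonlite::write_json(list(min = bfit$min, max = bfit$max,
                                  log_t50 = bfit$log_t50, slope = bfit$slope,
                                  t95_s = bfit$t95_s,
                                  n_transitions = bts$n_transitions,
                                  flags = bfit$flags),
                             f_bu, auto_unbox = TRUE, digits = 10)
        m$files <- c(m$files, list(file_entry(f_bu)))
        m$results$buildup_t95_s <- bfit$t95_s
      }
    }
    if (isTRUE(config$analyses$pac)) {
      ab <- filterbank_hilbert(rec, centers = sort(unique(c(seq(2, 20, 2),
                                                            seq(22, 50, 2)))))
      cmg <- comodulogram(ab, sub_hyp, schedule, state = "WAKE",
                          seed = stage_seed + 4L)
      f_pac <- file.path(dir, "comodulogram.csv")
      cm_df <- do.call(rbind, lapply(names(cmg$pacz), function(dp) {
        mtx <- cmg$pacz[[dp]]
        data.frame(day_phase = dp,
                   phase_f = rep(cmg$phase_centers, times = length(cmg$amp_centers)),
                   amp_f = rep(cmg$amp_centers, each = length(cmg$phase_centers)),
                   median_pacz = as.numeric(mtx))
      }))
      utils::write.csv(cm_df, f_pac, row.names = FALSE)
      m$files <- c(m$files, list(file_entry(f_pac)))
    }
  }
  res$manifest <- m
  res
}

cosinor_json <- function(f) {
  list(M = f$M, amplitude = f$amplitude, theta_deg = f$theta_deg,
       acrophase_lag_deg = f$acrophase_lag_deg, period_h = f$period_h,
       p_zero_amplitude = f$p_zero_amplitude, n = f$n)
}
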