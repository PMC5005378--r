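#' Exponential decay fit of NREM slow-wave activity
#'
#' Fits `SWA(t) = SWA0 * exp(-t / tau) + SWAinf` by nonlinear least squares
#' (Levenberg-Marquardt), where `t` is NREM sleep time accumulated from the
#' first NREM incidence — the Process-S discharge of the two-process model.
#' Deterministic starting values: `SWAinf = last bin`, `SWA0 = first - last
#' bin`, `tau = span / 3`; bounds `tau > 0`, `SWAinf >= 0`.
#'
#' @param t_h accumulated NREM time at bin centers, hours.
#' @param swa normalized SWA per bin (missing bins dropped).
#' @return a `swa_decay_fit`: `SWA0`, `tau_h`, `SWAinf`, per-parameter
#'   approximate standard errors and p-values, `rss`, `df`, the
#'   model-vs-constant F test, and `flags` (`converged`, `degenerate`).
#' @export
swa_decay_fit <- function(t_h, swa) {
  ok <- is.finite(t_h) & is.finite(swa)
  t_h <- t_h[ok]; swa <- swa[ok]
  n <- length(swa)
  if (n < 10) stop("need >= 10 non-missing bins")
  o <- order(t_h); t_h <- t_h[o]; swa <- swa[o]
  start <- c(SWA0 = max(swa[1] - swa[n], 1e-3), tau_h = diff(range(t_h)) / 3,
             SWAinf = max(swa[n], 0))
  fit <- minpack.lm::nlsLM(
    swa ~ SWA0 * exp(-t_h / tau_h) + SWAinf,
    start = as.list(start),
    lower = c(SWA0 = -Inf, tau_h = 1e-6, SWAinf = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 3))
  rss <- sum(stats::residuals(fit)^2)
  df <- n - 3
  ss0 <- sum((swa - mean(swa))^2)
  Fm <- ((ss0 - rss) / 2) / (rss / df)
  conv <- fit$convInfo$isConv %||% TRUE
  degenerate <- (is.finite(se[1]) && abs(cf[["SWA0"]]) < 2 * se[1]) ||
    cf[["tau_h"]] <= 2e-6 || !conv
  structure(list(SWA0 = cf[["SWA0"]], tau_h = cf[["tau_h"]],
                 SWAinf = cf[["SWAinf"]], se = se, rss = rss, df = df, n = n,
                 F_model = Fm,
                 p_model = stats::pf(Fm, 2, df, lower.tail = FALSE),
                 p_params = 2 * stats::pt(abs(cf / se), df, lower.tail = FALSE),
                 flags = list(converged = conv, degenerate = degenerate),
                 data = data.frame(t_h = t_h, swa = swa)),
            class = "swa_decay_fit")
}

#' @export
print.swa_decay_fit <- function(x, ...) {
  cat(sprintf("SWA decay fit: SWA0 = %.4g, tau = %.4g h, SWAinf = %.4g (n = %d)\n",
              x$SWA0, x$tau_h, x$SWAinf, x$n))
  if (x$flags$degenerate) cat("  [flagged: degenerate or non-converged]\n")
  invisible(x)
}

#' Logistic fit of SWA buildup at wake->NREM transitions
#'
#' Fits the 4-parameter logistic in log10 time,
#' `y(t) = min + (max - min) / (1 + 10^((log_t50 - log10 t) * slope))`,
#' to transition-aligned SWA in 2-s bins averaged over transitions.
#'
#' @param t_s time since transition at bin centers, seconds (> 0).
#' @param y mean SWA per bin.
#' @return a `buildup_fit`: `min`, `max`, `log_t50`, `slope`, `rss`, `df`,
#'   `t95_s` (time to reach 95% of the min-to-max span), and `flags`.
#' @export
buildup_fit <- function(t_s, y) {
  ok <- is.finite(t_s) & is.finite(y) & t_s > 0
  t_s <- t_s[ok]; y <- y[ok]
  n <- length(y)
  if (n < 6) stop("need >= 6 bins")
  q <- max(2L, floor(n / 4))
  y_lo <- mean(y[seq_len(q)]); y_hi <- mean(y[(n - q + 1):n])
  mid <- (y_lo + y_hi) / 2
  t50_0 <- t_s[which.min(abs(y - mid))]
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ ymin + (ymax - ymin) / (1 + 10^((log_t50 - log10(t_s)) * slope)),
    start = list(ymin = y_lo, ymax = y_hi, log_t50 = log10(max(t50_0, 1e-3)),
                 slope = 2),
    lower = c(ymin = -Inf, ymax = -Inf, log_t50 = -3, slope = 0.01),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # flat input: the span is ~0 and the rise parameters are unidentifiable
    m <- mean(y)
    return(structure(list(min = m, max = m, log_t50 = NA_real_,
                          slope = NA_real_, rss = sum((y - m)^2), df = n - 4,
                          n = n, t95_s = NA_real_,
                          flags = list(converged = FALSE, degenerate = TRUE),
                          data = data.frame(t_s = t_s, y = y)),
                     class = "buildup_fit"))
  }
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  conv <- fit$convInfo$isConv %||% TRUE
  degenerate <- abs(cf[["ymax"]] - cf[["ymin"]]) <
    1e-3 * max(abs(cf[["ymax"]]), 1e-12) || !conv
  # time at which the fitted curve reaches 95% of (max - min)
  t95 <- 10^(cf[["log_t50"]] - log10(1 / 19) / cf[["slope"]])
  structure(list(min = cf[["ymin"]], max = cf[["ymax"]],
                 log_t50 = cf[["log_t50"]], slope = cf[["slope"]],
                 rss = rss, df = n - 4, n = n, t95_s = t95,
                 flags = list(converged = conv, degenerate = degenerate),
                 data = data.frame(t_s = t_s, y = y)),
            class = "buildup_fit")
}

#' @export
print.buildup_fit <- function(x, ...) {
  cat(sprintf("SWA buildup fit: min = %.4g, max = %.4g, t50 = %.3g s, slope = %.3g (95%% rise by %.1f s)\n",
              x$min, x$max, 10^x$log_t50, x$slope, x$t95_s))
  if (x$flags$degenerate) cat("  [flagged: degenerate or non-converged]\n")
  invisible(x)
}

# model registry for the extra-sum-of-squares machinery
hs_models <- list(
  decay = list(
    pars = c("SWA0", "tau_h", "SWAinf"),
    fun = function(t, p) p[["SWA0"]] * exp(-t / p[["tau_h"]]) + p[["SWAinf"]],
    lower = c(SWA0 = -Inf, tau_h = 1e-6, SWAinf = 0),
    start = function(t, y) {
      o <- order(t)
      c(SWA0 = max(y[o][1] - y[o][length(y)], 1e-3),
        tau_h = diff(range(t)) / 3, SWAinf = max(y[o][length(y)], 0))
    }),
  buildup = list(
    pars = c("ymin", "ymax", "log_t50", "slope"),
    fun = function(t, p) p[["ymin"]] + (p[["ymax"]] - p[["ymin"]]) /
      (1 + 10^((p[["log_t50"]] - log10(t)) * p[["slope"]])),
    lower = c(ymin = -Inf, ymax = -Inf, log_t50 = -3, slope = 0.01),
    start = function(t, y) {
      n <- length(y); q <- max(2L, floor(n / 4)); o <- order(t)
      y_lo <- mean(y[o][seq_len(q)]); y_hi <- mean(y[o][(n - q + 1):n])
      t50 <- t[o][which.min(abs(y[o] - (y_lo + y_hi) / 2))]
      c(ymin = y_lo, ymax = y_hi, log_t50 = log10(max(t50, 1e-3)), slope = 2)
    })
)

fit_pooled <- function(model, t_list, y_list, free) {
  m <- hs_models[[model]]
  shared <- setdiff(m$pars, free)
  g <- length(t_list)
  # parameter vector layout: shared once, free parameters per dataset
  p_names <- c(shared, unlist(lapply(free, function(f) paste0(f, "_", seq_len(g)))))
  t_all <- unlist(t_list); y_all <- unlist(y_list)
  s0 <- m$start(t_all, y_all)
  start <- c(s0[shared], unlist(lapply(free, function(f)
    stats::setNames(rep(s0[[f]], g), paste0(f, "_", seq_len(g))))))
  lower <- c(m$lower[shared], unlist(lapply(free, function(f)
    stats::setNames(rep(m$lower[[f]], g), paste0(f, "_", seq_len(g))))))
  resid_fn <- function(p) {
    p <- stats::setNames(p, p_names)
    unlist(lapply(seq_len(g), function(i) {
      pi <- c(p[shared], stats::setNames(p[paste0(free, "_", i)], free))
      y_list[[i]] - m$fun(t_list[[i]], pi)
    }))
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  list(rss = sum(fit$fvec^2), k = length(start), par = stats::setNames(fit$par, p_names))
}

#' Extra-sum-of-squares F test between conditions
#'
#' Compares a null fit in which the parameters in `free` are shared between
#' the two datasets against an alternative fit in which they differ
#' (parameters not in `free` are shared in both models):
#' `F = [(SS_shared - SS_separate) / (df_sh - df_sep)] / [SS_separate / df_sep]`.
#'
#' @param data_a,data_b lists with elements `t` and `y` (decay: accumulated
#'   NREM hours vs SWA; buildup: seconds vs SWA).
#' @param model `"decay"` or `"buildup"`.
#' @param free parameters allowed to differ under the alternative; default
#'   all parameters of the model.
#' @return an `ftest_result`: `F`, `df_num`, `df_den`, `p`, both residual
#'   sums of squares, and the fitted parameter vectors.
#' @export
compare_fits_ftest <- function(data_a, data_b, model = c("decay", "buildup"),
                               free = NULL) {
  model <- match.arg(model)
  free <- free %||% hs_models[[model]]$pars
  if (!all(free %in% hs_models[[model]]$pars))
    stop("unknown parameter(s): ", paste(setdiff(free, hs_models[[model]]$pars),
                                         collapse = ", "))
  tl <- list(data_a$t, data_b$t); yl <- list(data_a$y, data_b$y)
  null_fit <- fit_pooled(model, tl, yl, free = character(0))
  alt_fit <- fit_pooled(model, tl, yl, free = free)
  n_tot <- length(unlist(yl))
  df_sep <- n_tot - alt_fit$k
  df_sh <- n_tot - null_fit$k
  if (alt_fit$rss <= 0) {
    warning("zero residual sum of squares in the separate fit; F degenerate")
    return(structure(list(F = NA_real_, df_num = df_sh - df_sep,
                          df_den = df_sep, p = NA_real_, degenerate = TRUE),
                     class = "ftest_result"))
  }
  Fz <- ((null_fit$rss - alt_fit$rss) / (df_sh - df_sep)) / (alt_fit$rss / df_sep)
  Fz <- max(Fz, 0)
  structure(list(F = Fz, df_num = df_sh - df_sep, df_den = df_sep,
                 p = stats::pf(Fz, df_sh - df_sep, df_sep, lower.tail = FALSE),
                 rss_shared = null_fit$rss, rss_separate = alt_fit$rss,
                 par_shared = null_fit$par, par_separate = alt_fit$par,
                 free = free, model = model, degenerate = FALSE),
            class = "ftest_result")
}

#' @export
print.ftest_result <- function(x, ...) {
  cat(sprintf("Extra-sum-of-squares F test (%s; free: %s): F(%d, %d) = %.4g, p = %.4g\n",
              x$model, paste(x$free, collapse = ", "), x$df_num, x$df_den,
              x$F, x$p))
  invisible(x)
}

#' NREM SWA series on accumulated-sleep time
#'
#' Builds the decay-fit input from a recording and hypnogram: per-epoch
#' 1-3 Hz power of NREM epochs, placed on the accumulated-NREM-time axis
#' (hours since the first NREM epoch of the window), binned into
#' `bin_s`-second bins of NREM time, optionally normalized by the median
#' over photophase NREM epochs.
#'
#' @param rec preprocessed `recording`; @param hyp aligned `hypnogram`.
#' @param schedule optional override of `rec$schedule`.
#' @param band SWA band (default `c(1, 3)` Hz, the homeostasis window).
#' @param bin_s bin width of accumulated NREM time (default 600 s).
#' @param norm `"median_photophase"` (default) or `"none"`.
#' @param exclude_rise_s NREM seconds dropped after each wake->NREM
#'   transition (default 60): the logistic-buildup window belongs to the
#'   buildup model and would bias the decay fit.
#' @return data.frame (t_h, swa, n_epochs).
#' @export
swa_nrem_series <- function(rec, hyp, schedule = NULL, band = c(1, 3),
                            bin_s = 600, norm = c("median_photophase", "none"),
                            exclude_rise_s = 60) {
  norm <- match.arg(norm)
  schedule <- schedule %||% rec$schedule
  ev <- epoch(rec, schedule)
  n_ep <- min(nrow(ev), length(hyp))
  p <- epoch_psd(rec, ev[seq_len(n_ep), ])
  bp <- band_sum(p, band[1], band[2])
  st <- unclass(hyp)[seq_len(n_ep)]
  is_n <- st == "NREM"
  if (!any(is_n)) stop("no NREM epochs")
  use <- is_n                                # epochs contributing SWA values
  if (exclude_rise_s > 0) {
    # rise windows belong to the buildup model: excluded from the fitted
    # values but still advance the accumulated-NREM-time clock
    runs <- rle(st)
    r_ends <- cumsum(runs$lengths); r_starts <- r_ends - runs$lengths + 1L
    k <- ceiling(exclude_rise_s / 4)
    for (j in which(runs$values == "NREM")) {
      prev <- if (j == 1) "WAKE" else runs$values[j - 1]
      if (prev != "WAKE") next
      drop_to <- min(r_starts[j] + k - 1L, r_ends[j])
      use[r_starts[j]:drop_to] <- FALSE
    }
    if (!any(use)) stop("no NREM epochs outside the rise windows")
  }
  first <- which(is_n)[1]
  keep <- seq_len(n_ep) >= first
  ts_h <- (cumsum(is_n & keep) - 0.5 * (is_n & keep)) * 4 / 3600  # mid-epoch
  if (norm == "median_photophase" && !is.null(schedule)) {
    ph <- phase_of_day(schedule, ev$t_start_s[seq_len(n_ep)])
    ref <- stats::median(bp[use & ph == "photophase"])
    if (is.finite(ref) && ref > 0) bp <- bp / ref
  }
  sel <- which(use & keep)
  bin <- floor(ts_h[sel] * 3600 / bin_s)
  cnt <- as.numeric(table(bin))
  v <- as.numeric(rowsum(bp[sel], bin)) / cnt
  data.frame(t_h = (sort(unique(bin)) + 0.5) * bin_s / 3600, swa = v,
             n_epochs = cnt)
}

#' Transition-aligned SWA buildup series
#'
#' Finds wake->NREM transitions (NREM onset after at least `min_wake_s` of
#' WAKE, with at least `window_s` of uninterrupted NREM after onset), takes
#' 1-3 Hz power in `bin_s`-second bins over `[0, window_s)` from each onset,
#' and averages across transitions.
#'
#' @param rec preprocessed `recording`; @param hyp aligned `hypnogram`.
#' @param band SWA band (default `c(1, 3)`).
#' @param bin_s bin width, seconds (default 2).
#' @param window_s post-transition window (default 60).
#' @param min_wake_s minimum preceding wake (default 60).
#' @return list: `mean` data.frame (t_s bin centers, y), `matrix`
#'   (transitions x bins), `n_transitions`.
#' @export
transition_swa <- function(rec, hyp, band = c(1, 3), bin_s = 2,
                           window_s = 60, min_wake_s = 60) {
  runs <- rle(as.vector(unclass(hyp)))
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  need_w <- ceiling(min_wake_s / 4); need_n <- ceiling(window_s / 4)
  trans <- which(runs$values == "NREM" & runs$lengths >= need_n &
                   c(FALSE, (runs$values == "WAKE" & runs$lengths >= need_w)[-length(runs$values)]))
  if (length(trans) < 5) stop("fewer than 5 qualifying wake->NREM transitions")
  n_bins <- floor(window_s / bin_s)
  mat <- t(vapply(trans, function(j) {
    s0 <- (starts[j] - 1L) * 4L * rec$fs
    sub <- new_recording(rec$eeg[s0 + seq_len(window_s * rec$fs)],
                         rec$emg[s0 + seq_len(window_s * rec$fs)], fs = rec$fs)
    stft_band_power(sub, band, bin_s)[seq_len(n_bins)]
  }, numeric(n_bins)))
  list(mean = data.frame(t_s = (seq_len(n_bins) - 0.5) * bin_s,
                         y = colMeans(mat)),
       matrix = mat, n_transitions = length(trans))
}
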