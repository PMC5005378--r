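#' Chi-square periodogram (Sokolove-Bushell)
#'
#' For each candidate period of `P` whole bins the series is folded modulo
#' `P` and
#' `Qp = N * (sum_h (M_h - Mbar)^2 / P) / (sum_i (x_i - xbar)^2 / N)`
#' with `M_h` the column means; under the no-rhythm null `Qp` is chi-square
#' with `P - 1` degrees of freedom, giving the per-period significance
#' threshold at level `alpha`.
#'
#' @param x uniformly binned series (e.g. 1-min activity or 10-min power).
#' @param bin_min bin width in minutes.
#' @param period_range_h candidate period range in hours (default 16-32,
#'   bracketing all light-dark schedules of interest); the grid steps by one
#'   bin.
#' @param alpha significance level (default 0.01).
#' @return a `chi2_periodogram`: data.frame (period_h, Qp, df, threshold,
#'   significant) with attributes `peak_period_h` (significant maximum of
#'   `Qp - threshold`, or `NA`) and `alpha`.
#' @export
chi2_periodogram <- function(x, bin_min = 1, period_range_h = c(16, 32),
                             alpha = 0.01) {
  x <- as.numeric(x)
  n <- length(x)
  bin_h <- bin_min / 60
  p_lo <- ceiling(period_range_h[1] / bin_h)
  p_hi <- floor(period_range_h[2] / bin_h)
  if (p_lo > p_hi) stop("period grid finer than the bin width")
  if (p_hi > n / 2) stop("period range exceeds half the data span")
  ssx <- sum((x - mean(x))^2)
  idx <- seq_len(n) - 1L
  rows <- lapply(p_lo:p_hi, function(P) {
    h <- idx %% P
    M <- as.numeric(rowsum(x, h)) / tabulate(h + 1L, P)
    ssm <- sum((M - mean(M))^2)
    Qp <- if (ssx > 0) n * (ssm / P) / (ssx / n) else 0
    thr <- stats::qchisq(1 - alpha, df = P - 1)
    data.frame(period_h = P * bin_h, Qp = Qp, df = P - 1L, threshold = thr,
               significant = Qp > thr)
  })
  out <- do.call(rbind, rows)
  # peak = largest Qp among significant periods (Qp itself, not the excess
  # over the threshold, whose P-dependence would bias the peak short)
  peak <- if (any(out$significant))
    out$period_h[out$significant][which.max(out$Qp[out$significant])]
  else NA_real_
  structure(out, class = c("chi2_periodogram", "data.frame"),
            peak_period_h = peak, alpha = alpha)
}

#' @export
print.chi2_periodogram <- function(x, ...) {
  pk <- attr(x, "peak_period_h")
  cat(sprintf("Chi-square periodogram: %d candidate periods %.2f-%.2f h, alpha = %g\n",
              nrow(x), min(x$period_h), max(x$period_h), attr(x, "alpha")))
  cat(if (is.na(pk)) "  no significant period\n"
      else sprintf("  significant peak at %.2f h\n", pk))
  invisible(x)
}

#' Actogram matrix: day x time-of-cycle folding of an activity series
#'
#' Folds a 1-min activity series at the zeitgeber (or free-running) period
#' into a matrix with one row per cycle — the numeric form of a single-plot
#' actogram, ready for CSV export or image plotting.
#'
#' @param act an `activity_series`.
#' @param period_h folding period in hours.
#' @return matrix (cycles x bins-per-cycle); incomplete trailing cycle
#'   padded with `NA`.
#' @export
actogram_matrix <- function(act, period_h) {
  bins <- round(period_h * 60)
  n_cyc <- ceiling(length(act$distance) / bins)
  t(vapply(seq_len(n_cyc), function(i) {
    idx <- ((i - 1) * bins + 1):min(i * bins, length(act$distance))
    c(act$distance[idx], rep(NA_real_, bins - length(idx)))
  }, numeric(bins)))
}

#' Single cosinor fit (fixed angular frequency)
#'
#' Least-squares fit of `y = M + A cos(omega t + theta)` through its
#' linearization `y = M + beta x + gamma z` with `x = cos(omega t)`,
#' `z = sin(omega t)`, `beta = A cos(theta)`, `gamma = -A sin(theta)`.
#' The angular frequency is fixed by the zeitgeber period, not fitted.
#' The zero-amplitude hypothesis (`beta = gamma = 0`) is tested with the
#' standard F statistic on (2, n - 3) degrees of freedom.
#'
#' @param t_h times in hours (>= 2 full cycles advised); missing `y` values
#'   are dropped (state-masked series are inherently gappy).
#' @param y series values.
#' @param period_h rhythm period in hours (`omega = 360 / period_h` deg/h).
#' @return a `cosinor_fit`: mesor `M`, `amplitude`, `theta_deg` (phase in
#'   degrees, `(-180, 180]`), `acrophase_lag_deg` (peak lag after t = 0 in
#'   `[0, 360)`), `beta`, `gamma`, `omega_deg_h`, `sigma2`, `p_zero_amplitude`,
#'   `n`, and the residual sum of squares.
#' @export
cosinor_fit <- function(t_h, y, period_h) {
  ok <- is.finite(t_h) & is.finite(y)
  t_h <- t_h[ok]; y <- y[ok]
  n <- length(y)
  if (n < 4) stop("need at least 4 observations")
  w <- 2 * pi / period_h
  x <- cos(w * t_h); z <- sin(w * t_h)
  X <- cbind(1, x, z)
  if (qr(X)$rank < 3) stop("singular cosinor design (all bins at the same phase)")
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  beta <- cf[2]; gam <- cf[3]
  A <- sqrt(beta^2 + gam^2)
  theta <- atan2(-gam, beta) * 180 / pi
  ss1 <- sum(fit$residuals^2)
  ss0 <- sum((y - mean(y))^2)
  Fz <- ((ss0 - ss1) / 2) / (ss1 / (n - 3))
  structure(list(M = unname(cf[1]), amplitude = unname(A),
                 theta_deg = unname(theta),
                 acrophase_lag_deg = unname((-theta) %% 360),
                 beta = unname(beta), gamma = unname(gam),
                 omega_deg_h = 360 / period_h, period_h = period_h,
                 sigma2 = ss1 / (n - 3), rss = ss1, n = n,
                 F_zero_amplitude = Fz,
                 p_zero_amplitude = stats::pf(Fz, 2, n - 3, lower.tail = FALSE)),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("Cosinor (period %.3g h): M = %.4g, A = %.4g, theta = %.1f deg (peak lag %.1f deg)\n",
              x$period_h, x$M, x$amplitude, x$theta_deg, x$acrophase_lag_deg))
  cat(sprintf("  zero-amplitude test: F(2, %d) = %.3g, p = %.4g\n",
              x$n - 3, x$F_zero_amplitude, x$p_zero_amplitude))
  invisible(x)
}

#' Population-mean (group) cosinor with condition comparisons
#'
#' Population estimates from per-subject cosinor fits: the subject
#' `(beta, gamma)` pairs are averaged, the population amplitude and
#' acrophase are recovered from the mean vector, and the bivariate
#' between-subject covariance yields (i) the Hotelling-type F test of zero
#' population amplitude and (ii) an elliptical confidence region for
#' `(beta, gamma)`.  Conditions are compared pairwise with the two-sample
#' Hotelling T2 on `(beta, gamma)` (joint amplitude/acrophase test),
#' Bonferroni-corrected over pairs.
#'
#' @param fits_by_condition named list; each element a list of >= 3
#'   `cosinor_fit` objects (one per subject) sharing the same `omega`.
#' @param conf confidence level for the region (default 0.95).
#' @return a `group_cosinor`: per-condition `estimates` (data.frame) and
#'   `pairwise` comparisons (data.frame with Hotelling F, df, p, p_adj).
#' @export
group_cosinor <- function(fits_by_condition, conf = 0.95) {
  stopifnot(is.list(fits_by_condition), length(fits_by_condition) >= 1)
  omegas <- unlist(lapply(fits_by_condition, function(fs)
    vapply(fs, `[[`, numeric(1), "omega_deg_h")))
  if (length(unique(round(omegas, 9))) != 1)
    stop("all fits in a comparison must share the same angular frequency")
  per_cond <- lapply(fits_by_condition, function(fs) {
    if (length(fs) < 3) stop("need >= 3 subjects per condition")
    bg <- t(vapply(fs, function(f) c(f$beta, f$gamma), numeric(2)))
    n <- nrow(bg)
    m <- colMeans(bg)
    S <- stats::cov(bg)
    T2 <- n * drop(t(m) %*% solve(S) %*% m)
    Fz <- (n - 2) / (2 * (n - 1)) * T2
    list(n = n, mean = m, cov = S, M = mean(vapply(fs, `[[`, 0, "M")),
         amplitude = sqrt(sum(m^2)),
         theta_deg = atan2(-m[2], m[1]) * 180 / pi,
         F_zero = Fz, p_zero = stats::pf(Fz, 2, n - 2, lower.tail = FALSE),
         region_rhs = 2 * (n - 1) / (n * (n - 2)) *
           stats::qf(conf, 2, n - 2))
  })
  est <- do.call(rbind, lapply(names(per_cond), function(nm) {
    p <- per_cond[[nm]]
    data.frame(condition = nm, n = p$n, mesor = p$M, amplitude = p$amplitude,
               theta_deg = p$theta_deg,
               acrophase_lag_deg = (-p$theta_deg) %% 360,
               F_zero_amplitude = p$F_zero, p_zero_amplitude = p$p_zero)
  }))
  pw <- NULL
  cn <- names(per_cond)
  if (length(cn) >= 2) {
    pairs <- utils::combn(cn, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- per_cond[[pairs[1, j]]]; b <- per_cond[[pairs[2, j]]]
      n1 <- a$n; n2 <- b$n
      Sp <- ((n1 - 1) * a$cov + (n2 - 1) * b$cov) / (n1 + n2 - 2)
      d <- a$mean - b$mean
      T2 <- (n1 * n2) / (n1 + n2) * drop(t(d) %*% solve(Sp) %*% d)
      Fz <- (n1 + n2 - 3) / (2 * (n1 + n2 - 2)) * T2
      data.frame(cond_a = pairs[1, j], cond_b = pairs[2, j], F = Fz,
                 df1 = 2, df2 = n1 + n2 - 3,
                 p = stats::pf(Fz, 2, n1 + n2 - 3, lower.tail = FALSE))
    }))
    pw$p_adj <- pmin(1, pw$p * nrow(pw))     # Bonferroni over pairs
  }
  structure(list(estimates = est, pairwise = pw, per_condition = per_cond,
                 conf = conf), class = "group_cosinor")
}

#' Does the group confidence region cover a (beta, gamma) point?
#'
#' Evaluates whether `(beta, gamma) = (A cos theta, -A sin theta)` lies
#' inside the elliptical `conf`-level region of a condition's population
#' mean — the coverage check used in simulation tests.
#'
#' @param gc a `group_cosinor`.
#' @param condition condition name.
#' @param amplitude,theta_deg the point, in amplitude/phase form.
#' @return logical.
#' @export
cosinor_region_covers <- function(gc, condition, amplitude, theta_deg) {
  p <- gc$per_condition[[condition]]
  x <- c(amplitude * cos(theta_deg * pi / 180),
         -amplitude * sin(theta_deg * pi / 180))
  d <- p$mean - x
  drop(t(d) %*% solve(p$cov) %*% d) <= p$region_rhs
}

#' @export
print.group_cosinor <- function(x, ...) {
  cat("Group (population-mean) cosinor\n")
  print(x$estimates, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("Pairwise condition comparisons (Hotelling T2 on (beta, gamma)):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
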