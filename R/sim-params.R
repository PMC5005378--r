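#' Simulation parameters for the synthetic-data generator
#'
#' Bundles every ground-truth parameter of the generator: phase-of-day
#' dependent vigilance-state transition probabilities (first-order chain on
#' 4-s epochs), state-specific band amplitudes, theta-phase -> gamma-amplitude
#' coupling depth, circadian (zeitgeber-period) modulation of band power,
#' the two-process slow-wave-activity (SWA) envelope, and broadband noise.
#'
#' Transition matrices are row-stochastic over (WAKE, NREM, REM); REM is
#' reachable only from NREM or REM, a biological constraint the constructor
#' enforces.  Defaults encode a nocturnal animal: sleep-favouring rates in the
#' photophase, wake-favouring in the scotophase.
#'
#' The SWA envelope is `SWA0 * exp(-t_s / tau) + SWAinf` over NREM time `t_s`
#' accumulated within the current zeitgeber cycle, multiplied at each
#' wake->NREM transition by the logistic rise
#' `min + (max - min) / (1 + 10^((log_t50 - log10(t)) * slope))`
#' (t in seconds since the transition), reaching ~96% of its span by 50 s at
#' the default `log_t50 = log10(20)`, `slope = 3.5`.
#'
#' @param trans_photo,trans_scoto 3x3 row-stochastic transition matrices
#'   (rows/cols WAKE, NREM, REM) applied per 4-s epoch in the photophase and
#'   scotophase respectively.
#' @param amp_map named list `state -> c(swa=, theta=, gamma=)` of oscillation
#'   amplitudes (a.u.).
#' @param coupling_strength depth `kappa >= 0` of theta-phase modulation of
#'   gamma amplitude during WAKE; `kappa = 0` gives statistically uncoupled
#'   phase and amplitude.
#' @param circadian_mod named list `band -> c(rel_amp=, acrophase_h=)`:
#'   relative power modulation at the zeitgeber period and peak time in hours
#'   after lights-off.  Use `rel_amp = 0` to silence a band's rhythm.
#' @param swa_decay `c(SWA0=, tau_h=, SWAinf=)` of the decay envelope
#'   (dimensionless multipliers; tau in hours).
#' @param buildup `c(min=, max=, log_t50=, slope=)` of the logistic rise
#'   (log_t50 = log10 seconds).
#' @param noise_sd standard deviation of the additive broadband Gaussian
#'   noise (signal units).
#' @param emg_rms per-state EMG root-mean-square, `c(WAKE=, NREM=, REM=)`.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(
    trans_photo = rbind(WAKE = c(0.950, 0.050, 0.000),
                        NREM = c(0.030, 0.950, 0.020),
                        REM  = c(0.060, 0.010, 0.930)),
    trans_scoto = rbind(WAKE = c(0.985, 0.015, 0.000),
                        NREM = c(0.050, 0.930, 0.020),
                        REM  = c(0.080, 0.005, 0.915)),
    amp_map = list(WAKE = c(swa = 0.25, theta = 1.00, gamma = 0.50),
                   NREM = c(swa = 1.60, theta = 0.30, gamma = 0.15),
                   REM  = c(swa = 0.20, theta = 1.40, gamma = 0.30)),
    coupling_strength = 0.4,
    circadian_mod = list(theta = c(rel_amp = 0.4, acrophase_h = 5),
                         gamma = c(rel_amp = 0.4, acrophase_h = 5)),
    swa_decay = c(SWA0 = 1.5, tau_h = 1.0, SWAinf = 1.0),
    buildup = c(min = 0.3, max = 1.0, log_t50 = log10(20), slope = 3.5),
    noise_sd = 0.3,
    emg_rms = c(WAKE = 1.0, NREM = 0.2, REM = 0.1)) {
  for (tm in list(trans_photo, trans_scoto)) {
    if (!all(dim(tm) == c(3, 3))) stop("transition matrices must be 3x3")
    if (any(tm < 0) || any(tm > 1)) stop("transition probabilities must be in [0, 1]")
    if (any(abs(rowSums(tm) - 1) > 1e-9)) stop("transition matrix rows must sum to 1")
    if (tm[1, 3] > 0) stop("REM cannot be entered from WAKE (WAKE->REM probability must be 0)")
  }
  if (coupling_strength < 0) stop("coupling_strength must be >= 0")
  if (swa_decay[["tau_h"]] <= 0) stop("tau_h must be > 0")
  if (buildup[["max"]] < buildup[["min"]]) stop("buildup max must be >= min")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  dimnames(trans_photo) <- dimnames(trans_scoto) <- list(vstates, vstates)
  structure(list(trans_photo = trans_photo, trans_scoto = trans_scoto,
                 amp_map = amp_map, coupling_strength = coupling_strength,
                 circadian_mod = circadian_mod, swa_decay = swa_decay,
                 buildup = buildup, noise_sd = noise_sd, emg_rms = emg_rms),
            class = "sim_params")
}

#' Stationary state distribution of a transition matrix
#'
#' Left-eigenvector stationary distribution of a row-stochastic chain; the
#' analytic long-run state fractions the simulated hypnograms converge to.
#'
#' @param tm 3x3 row-stochastic matrix.
#' @return named numeric vector over (WAKE, NREM, REM) summing to 1.
#' @export
stationary_distribution <- function(tm) {
  e <- eigen(t(tm))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(v, vstates)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic-data parameters\n")
  cat("  coupling kappa:", x$coupling_strength,
      " noise sd:", x$noise_sd, "\n")
  cat("  SWA decay: SWA0 =", x$swa_decay[["SWA0"]],
      ", tau =", x$swa_decay[["tau_h"]], "h, SWAinf =",
      x$swa_decay[["SWAinf"]], "\n")
  cat("  photophase stationary:",
      paste(sprintf("%s %.2f", vstates, stationary_distribution(x$trans_photo)),
            collapse = ", "), "\n")
  cat("  scotophase stationary:",
      paste(sprintf("%s %.2f", vstates, stationary_distribution(x$trans_scoto)),
            collapse = ", "), "\n")
  invisible(x)
}
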