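#' Simulate a locomotor-activity series
#'
#' Generates distance moved per 1-min bin as the rectified sum of a cosine at
#' the entrained period, a mesor, and Gaussian noise.  The cosine peak is
#' placed mid-scotophase (`acrophase_h` after lights-off), so with
#' `amplitude > mesor` activity concentrates in the dark portion of the cycle
#' — the entrained nocturnal pattern the rhythm analyses assume.
#'
#' @param schedule a `light_schedule`; sets the series duration.
#' @param entrained_period_h period of the activity rhythm in hours (usually
#'   the zeitgeber period).
#' @param amplitude,mesor cosine amplitude and rhythm-adjusted mean
#'   (arbitrary distance units, both `>= 0`).
#' @param seed integer RNG seed.
#' @param noise_sd Gaussian noise SD before rectification.
#' @param acrophase_h peak time in hours after lights-off; default
#'   mid-scotophase of the entrained period.
#' @return an object of class `activity_series`: data.frame with `t_min`
#'   (bin centers, minutes) and `distance` (>= 0).
#' @export
simulate_activity <- function(schedule, entrained_period_h = 24,
                              amplitude = 2, mesor = 1, seed = 1,
                              noise_sd = 0.5, acrophase_h = NULL) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (entrained_period_h <= 0) stop("entrained_period_h must be > 0")
  if (amplitude < 0 || mesor < 0) stop("amplitude and mesor must be >= 0")
  if (is.null(acrophase_h)) {
    pf <- if (schedule$dd) 0 else schedule$photofraction
    acrophase_h <- entrained_period_h * (1 - pf) / 2
  }
  n <- floor(schedule$duration_s / 60)
  t_min <- seq_len(n) - 0.5                         # bin centers
  x <- mesor + amplitude *
    cos(2 * pi * (t_min / 60 - acrophase_h) / entrained_period_h)
  with_seed(seed, {
    if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
  })
  structure(data.frame(t_min = t_min, distance = pmax(0, x)),
            class = c("activity_series", "data.frame"),
            period_h = entrained_period_h, acrophase_h = acrophase_h)
}
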