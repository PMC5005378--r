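#' Light-dark schedule
#'
#' Constructs a light schedule that tiles the time axis with alternating
#' scotophase (dark) and photophase (light) intervals of a fixed zeitgeber
#' period, starting dark at `lights_off_clock`.  Under constant darkness
#' (`dd = TRUE`) every timestamp maps to scotophase.
#'
#' Time inside the package is always seconds since the start of the recording,
#' and recordings are assumed to start at lights-off of the first cycle, the
#' convention all downstream phase-of-day lookups rely on.
#'
#' @param period_h zeitgeber period in hours (e.g. 24, 22, 21, 20); ignored
#'   when `dd = TRUE`.
#' @param photofraction fraction of the cycle that is light, in `[0, 1]`.
#'   0.5 for the symmetric LD x/x schedules.
#' @param n_days number of astronomic (24-h) days the schedule spans.
#' @param lights_off_clock clock time of lights-off, `"HH:MM"`; metadata only.
#' @param dd if `TRUE`, constant darkness.
#' @return an object of class `light_schedule`.
#' @examples
#' sch <- make_schedule(21, 0.5, n_days = 14)   # LD10.5/10.5
#' phase_of_day(sch, c(0, 10.4 * 3600, 10.6 * 3600))
#' @export
make_schedule <- function(period_h = 24, photofraction = 0.5, n_days = 1,
                          lights_off_clock = "8:30", dd = FALSE) {
  if (n_days < 1) stop("n_days must be >= 1")
  if (!dd) {
    if (!is.numeric(period_h) || period_h <= 0)
      stop("period_h must be positive")
    if (photofraction < 0 || photofraction > 1)
      stop("photofraction must be in [0, 1]")
  }
  structure(list(
    period_h = if (dd) NA_real_ else period_h,
    photofraction = if (dd) 0 else photofraction,
    n_days = n_days,
    lights_off_clock = lights_off_clock,
    dd = dd,
    duration_s = n_days * 24 * 3600
  ), class = "light_schedule")
}

#' Phase-of-day lookup
#'
#' Maps timestamps (seconds since schedule start = first lights-off) to
#' `"scotophase"` or `"photophase"`.  Each zeitgeber cycle starts dark:
#' the scotophase occupies the first `(1 - photofraction)` of the cycle.
#'
#' @param schedule a `light_schedule`.
#' @param t_s numeric vector of times in seconds.
#' @return character vector of phase labels.
#' @export
phase_of_day <- function(schedule, t_s) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (schedule$dd) return(rep("scotophase", length(t_s)))
  period_s <- schedule$period_h * 3600
  frac <- (t_s %% period_s) / period_s
  ifelse(frac < (1 - schedule$photofraction), "scotophase", "photophase")
}

#' Cycle index lookup
#'
#' Zeitgeber cycle number (0-based) for each timestamp; under DD a 24-h
#' pseudo-cycle is used so "day"-relative statistics remain defined.
#'
#' @inheritParams phase_of_day
#' @return integer vector of cycle indices.
#' @export
cycle_index <- function(schedule, t_s) {
  stopifnot(inherits(schedule, "light_schedule"))
  period_s <- if (schedule$dd) 24 * 3600 else schedule$period_h * 3600
  as.integer(floor(t_s / period_s))
}

#' @export
print.light_schedule <- function(x, ...) {
  if (x$dd) {
    cat("Light schedule: constant darkness (DD),", x$n_days, "days\n")
  } else {
    dark_h <- x$period_h * (1 - x$photofraction)
    cat(sprintf("Light schedule: LD %.3g/%.3g (period %.3g h), %d days, lights off %s\n",
                dark_h, x$period_h - dark_h, x$period_h, x$n_days,
                x$lights_off_clock))
  }
  invisible(x)
}

# seconds covered by the last n complete zeitgeber cycles that fit in
# [0, total_s); used by every "last 2 days of the stage" restriction
last_cycles_window <- function(schedule, total_s, n_cycles = 2) {
  period_s <- if (schedule$dd) 24 * 3600 else schedule$period_h * 3600
  n_complete <- floor(total_s / period_s)
  n_use <- min(n_cycles, n_complete)
  if (n_use < 1) return(c(0, total_s))
  c((n_complete - n_use) * period_s, n_complete * period_s)
}
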