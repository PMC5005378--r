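# internal helpers

# run expr with a private RNG stream; caller's .Random.seed is untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  expr
}

rms <- function(x) sqrt(mean(x^2))

# analytic signal via the FFT construction; x real, any length
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# circular (modulo) difference in degrees, result in (-180, 180]
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

vstates <- c("WAKE", "NREM", "REM")

stop_if_not_states <- function(x) {
  if (!all(x %in% vstates)) stop("states must be in {WAKE, NREM, REM}")
  invisible(x)
}
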