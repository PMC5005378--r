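#' Simulate a hypnogram
#'
#' Draws one vigilance-state label per 4-s epoch from a phase-of-day-dependent
#' first-order Markov chain over (WAKE, NREM, REM).  The photophase and
#' scotophase transition matrices come from [sim_params()]; REM is entered
#' only from NREM (enforced at construction).  Identical seeds give identical
#' label sequences.
#'
#' @param schedule a [make_schedule()] object; its duration sets the number
#'   of epochs.
#' @param params a [sim_params()] object.
#' @param seed integer RNG seed.
#' @param start_state initial state, default `"WAKE"`.
#' @param n_epochs optional override of the epoch count (defaults to
#'   `floor(duration / 4 s)`).
#' @return an object of class `hypnogram`: character state vector with
#'   attributes `epoch_s = 4`, `provenance = "simulated"`.
#' @export
simulate_hypnogram <- function(schedule, params = sim_params(), seed = 1,
                               start_state = "WAKE", n_epochs = NULL) {
  stopifnot(inherits(schedule, "light_schedule"), inherits(params, "sim_params"))
  stop_if_not_states(start_state)
  if (is.null(n_epochs)) n_epochs <- floor(schedule$duration_s / 4)
  if (n_epochs < 1) stop("schedule too short for a single 4-s epoch")
  phase <- phase_of_day(schedule, (seq_len(n_epochs) - 1) * 4)
  # precompute cumulative rows for both matrices
  cum_p <- t(apply(params$trans_photo, 1, cumsum))
  cum_s <- t(apply(params$trans_scoto, 1, cumsum))
  states <- integer(n_epochs)
  with_seed(seed, {
    u <- stats::runif(n_epochs)
    cur <- match(start_state, vstates)
    is_photo <- phase == "photophase"
    for (k in seq_len(n_epochs)) {
      states[k] <- cur
      cm <- if (is_photo[k]) cum_p else cum_s
      cur <- which(u[k] <= cm[cur, ])[1]
    }
  })
  new_hypnogram(vstates[states], provenance = "simulated")
}

#' Hypnogram constructor
#'
#' @param states character vector over (WAKE, NREM, REM), one per 4-s epoch.
#' @param provenance `"scored"` or `"simulated"`.
#' @param flags optional logical vector marking epochs scored on degenerate
#'   (all-zero) features.
#' @return a `hypnogram`.
#' @export
new_hypnogram <- function(states, provenance = c("scored", "simulated"),
                          flags = NULL) {
  provenance <- match.arg(provenance)
  stop_if_not_states(states)
  structure(states, epoch_s = 4, provenance = provenance, flags = flags,
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = vstates))
  cat(sprintf("Hypnogram: %d epochs of 4 s (%.2f h), %s\n", length(x),
              length(x) * 4 / 3600, attr(x, "provenance")))
  cat(sprintf("  %s: %d (%.1f%%)\n", names(tab), as.integer(tab),
              100 * as.integer(tab) / length(x)), sep = "")
  invisible(x)
}

#' @export
`[.hypnogram` <- function(x, i) {
  new_hypnogram(unclass(x)[i], attr(x, "provenance"),
                flags = if (!is.null(attr(x, "flags"))) attr(x, "flags")[i])
}

#' State fractions per phase of day
#'
#' @param hyp a `hypnogram`.
#' @param schedule the aligned `light_schedule`.
#' @return data.frame (phase, state, fraction).
#' @export
state_fractions <- function(hyp, schedule) {
  phase <- phase_of_day(schedule, (seq_along(hyp) - 1) * 4)
  out <- expand.grid(phase = unique(phase), state = vstates,
                     stringsAsFactors = FALSE)
  out$fraction <- mapply(function(p, s)
    mean(unclass(hyp)[phase == p] == s), out$phase, out$state)
  out
}
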