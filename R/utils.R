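# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so generators are pure
#' functions of their `seed` argument and never disturb the caller's RNG
#' stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-entity seed derivation from one master seed.
# Keeps results below 2^31 so seeds stay valid R integers.
child_seed <- function(seed, counter) {
  as.integer((as.double(seed) + 10007 * as.double(counter)) %% 2147483647)
}

stop_pavcond <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_pavcond(...)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Trapezoidal integral of a sampled trace over a half-open time window
#'
#' Integrates `values` (sampled at the times in `times`) over
#' `[window[1], window[2])`. Samples with `start <= t < end` contribute; a
#' sample at exactly the window end belongs to the next epoch and is
#' excluded (so, e.g., an airpuff response starting at the end of the
#' anticipatory window never leaks into it). The trace is linearly
#' interpolated at the window start when no sample falls there, and the
#' last subinterval is extended at the final included value so the
#' integral always spans the full window length (a constant trace `c`
#' integrates to exactly `c * (end - start)`).
#'
#' @param values numeric trace.
#' @param times sample times (seconds), strictly increasing, same length.
#' @param window numeric length-2, `c(start, end)` in the same time base.
#' @return The integral (value units x seconds).
#' @keywords internal
trapz_window <- function(values, times, window) {
  assert_that(length(values) == length(times), "values and times differ in length")
  assert_that(window[2] > window[1], "window end must exceed start")
  assert_that(window[1] >= times[1] - 1e-9 && window[2] <= times[length(times)] + 1e-9,
              "integration window [%g, %g] outside trace span [%g, %g]",
              window[1], window[2], times[1], times[length(times)])
  keep <- times >= window[1] - 1e-9 & times < window[2] - 1e-9
  tt <- times[keep]
  vv <- values[keep]
  if (!length(tt) || tt[1] > window[1] + 1e-12) {
    tt <- c(window[1], tt)
    vv <- c(stats::approx(times, values, xout = window[1], rule = 2)$y, vv)
  }
  n <- length(tt)
  base <- if (n > 1) sum(diff(tt) * (vv[-n] + vv[-1]) / 2) else 0
  base + vv[n] * (window[2] - tt[n])
}

head_ <- function(x, n) utils::head(x, n)
tail_ <- function(x, n) utils::tail(x, n)

# 9-significant-digit numeric formatting for text round-trips.
fmt_num <- function(x) formatC(x, digits = 9, format = "g")
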