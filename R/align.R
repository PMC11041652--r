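#' Align a continuous series into a trials x samples matrix
#'
#' Cuts one row per event out of a regularly sampled series. Row `t`
#' covers `[event_t - pre_s, event_t + total_s - pre_s)`; column
#' `t0_index + 1` is the sample at event onset (trial time 0). Sample
#' indices are mapped as `floor((t - t_start) * rate)`, so the result is
#' equivariant under a common time shift of the series and the events.
#'
#' @param values numeric series sampled at `window$sample_rate_hz`.
#' @param events event onset times, seconds.
#' @param window a [trace_window()].
#' @param t_start time of the first sample of `values`, seconds (default 0).
#' @param on_edge what to do with events whose trial window would leave the
#'   series: `"drop"` (default) drops them with a warning listing the
#'   events, `"error"` fails.
#' @return A `length(events)` (minus drops) x `window$n_samples` matrix with
#'   attribute `dropped_events` holding the onset times of dropped events.
#' @examples
#' w <- trace_window(10, pre_s = 1, total_s = 3)
#' x <- rep(0, 100); x[51] <- 1
#' m <- align_trials(x, events = 5.0, window = w)
#' which(m[1, ] == 1) - 1 == w$t0_index
#' @export
align_trials <- function(values, events, window, t_start = 0,
                         on_edge = c("drop", "error")) {
  stopifnot(inherits(window, "trace_window"))
  on_edge <- match.arg(on_edge)
  rate <- window$sample_rate_hz
  n <- window$n_samples
  # zero-based index of the first sample of each trial
  i0 <- floor((events - window$pre_s - t_start) * rate + 1e-9)
  ok <- i0 >= 0 & (i0 + n) <= length(values)
  if (any(!ok)) {
    msg <- sprintf("event(s) too close to series edge: %s",
                   paste(format(events[!ok]), collapse = ", "))
    if (on_edge == "error") stop_pavcond("%s", msg)
    warning(msg, call. = FALSE)
  }
  kept <- which(ok)
  out <- matrix(NA_real_, length(kept), n)
  for (k in seq_along(kept)) {
    out[k, ] <- values[(i0[kept[k]] + 1):(i0[kept[k]] + n)]
  }
  attr(out, "dropped_events") <- events[!ok]
  attr(out, "kept") <- kept
  out
}
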