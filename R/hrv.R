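#' Event-anchored RR window
#'
#' Returns the beats of the 20 s (by default) preceding an acquisition-end
#' event: all intervals whose end-time lies in
#' `(event_ms - window_s * 1000, event_ms]` (an interval straddling the
#' window start is included iff its end-time qualifies).
#'
#' @param series an [rr_series()].
#' @param event_ms event time, ms, within the recording span.
#' @param window_s window length, seconds (default 20).
#' @return numeric vector of RR intervals (ms) with attribute `window`
#'   `(start, end)` ms and attribute `insufficient` set `TRUE` when fewer
#'   than 2 beats fall inside.
#' @export
window_rr <- function(series, event_ms, window_s = 20) {
  stopifnot(inherits(series, "rr_series"), window_s > 0)
  span <- series$t_end_ms[length(series$t_end_ms)]
  if (event_ms < 0 || event_ms > span)
    stop("event lies outside the recording")
  sel <- series$t_end_ms > event_ms - window_s * 1000 & series$t_end_ms <= event_ms
  out <- series$rr_ms[sel]
  attr(out, "window") <- c(start = event_ms - window_s * 1000, end = event_ms)
  attr(out, "insufficient") <- sum(sel) < 2
  out
}

#' Mean heart rate of an RR window
#'
#' Time-weighted convention: `60000 * n / sum(rr_ms)` (equivalently
#' 60000 / mean RR), not the mean of instantaneous rates.
#'
#' @param rr_ms numeric vector of RR intervals, ms (>= 1 beat).
#' @return mean heart rate, beats per minute.
#' @export
mean_hr <- function(rr_ms) {
  if (length(rr_ms) < 1) stop("mean_hr needs at least one beat")
  60000 * length(rr_ms) / sum(rr_ms)
}

#' RMSSD of an RR window
#'
#' Root mean square of the successive differences between adjacent RR
#' intervals, the short-term HRV index of cardiac parasympathetic activity:
#' `sqrt(mean(diff(rr)^2))` over the `n - 1` successive differences.
#'
#' @param rr_ms numeric vector of RR intervals, ms (>= 2 beats).
#' @return RMSSD, ms.
#' @export
rmssd <- function(rr_ms) {
  if (length(rr_ms) < 2) stop("rmssd needs at least two beats")
  sqrt(mean(diff(rr_ms)^2))
}

#' HRV metrics for one acquisition-end event
#'
#' @param series an [rr_series()].
#' @param event_ms acquisition-end time, ms.
#' @param window_s window length, seconds.
#' @return list `mean_hr_bpm`, `rmssd_ms`, `n_beats`, `window`,
#'   `insufficient`; metrics are `NA` when fewer than 2 beats fall in the
#'   window.
#' @export
hrv_metrics <- function(series, event_ms, window_s = 20) {
  w <- window_rr(series, event_ms, window_s)
  if (isTRUE(attr(w, "insufficient"))) {
    return(list(mean_hr_bpm = NA_real_, rmssd_ms = NA_real_,
                n_beats = length(w), window = attr(w, "window"),
                insufficient = TRUE))
  }
  list(mean_hr_bpm = mean_hr(w), rmssd_ms = rmssd(w), n_beats = length(w),
       window = attr(w, "window"), insufficient = FALSE)
}
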