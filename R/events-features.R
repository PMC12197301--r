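# From per-segment classifications to a clean swallow event series and the
# five timing features used by the secretion estimator: swallow count over
# 300 s, counts per 100 s third, and the variance of swallow timing.

#' Swallow-labeled segments to an event series
#'
#' Each swallow-labeled segment contributes one event at its onset time
#' (the onset is what marks a swallow; segment midpoints are not used).
#' Events outside `[0, window_s)` are dropped.
#'
#' @param segments Segment tibble from [detect_segments()] (needs a
#'   `start_s` column).
#' @param labels Logical vector, one per segment: is this segment a
#'   swallow?
#' @param window_s Observation window length in seconds (default 300).
#' @return An event tibble with a single `time_s` column, sorted
#'   increasing.
#' @export
segments_to_events <- function(segments, labels, window_s = 300) {
  stopifnot(is.data.frame(segments), "start_s" %in% names(segments))
  if (length(labels) != nrow(segments)) {
    abort("`labels` must align one-to-one with `segments`.",
          class = "salivaflow_label_mismatch")
  }
  t <- sort(segments$start_s[as.logical(labels)])
  tibble(time_s = t[t >= 0 & t < window_s])
}

#' Suppress consecutive swallow detections
#'
#' Swallows detected within 2 s of one another are treated as one event
#' (a failed first swallow, or a split detection). The rule is a greedy
#' left-to-right pass: an event is kept iff its time minus the last
#' *kept* event's time exceeds `suppress_window_s`; the first event is
#' always kept. The result is idempotent and all inter-event gaps exceed
#' the suppression window.
#'
#' @param events Event tibble with `time_s`, sorted increasing.
#' @param suppress_window_s Suppression window in seconds (default 2).
#' @return Event tibble with the suppressed events removed.
#' @export
deduplicate_events <- function(events, suppress_window_s = 2.0) {
  stopifnot(is.data.frame(events), "time_s" %in% names(events),
            suppress_window_s >= 0)
  t <- events$time_s
  if (is.unsorted(t)) {
    abort("`events` must be sorted by time.", class = "salivaflow_unsorted")
  }
  if (!length(t)) return(tibble(time_s = numeric()))
  keep <- logical(length(t))
  keep[1] <- TRUE
  last <- t[1]
  for (i in seq_along(t)[-1]) {
    if (t[i] - last > suppress_window_s) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  tibble(time_s = t[keep])
}

#' Swallow-timing feature vector
#'
#' The five features of the secretion estimator: total swallow count in
#' the window, counts in the \[0,100), \[100,200), \[200,300) second bins
#' (half-open, so a swallow at exactly 100 s is counted once, in the
#' second bin), and the population variance (divisor n) of the event
#' times in seconds squared, defined as 0 for fewer than two events.
#'
#' @param events De-duplicated event tibble with `time_s`.
#' @param window_s Observation window (default 300; bins are thirds of it).
#' @return One-row tibble: `n_total`, `n_0_100`, `n_100_200`, `n_200_300`,
#'   `timing_variance`.
#' @export
extract_features <- function(events, window_s = 300) {
  stopifnot(is.data.frame(events), "time_s" %in% names(events))
  t <- events$time_s
  t <- t[t >= 0 & t < window_s]
  b <- window_s / 3
  v <- if (length(t) > 1) mean((t - mean(t))^2) else 0
  tibble(n_total = length(t),
         n_0_100 = sum(t < b),
         n_100_200 = sum(t >= b & t < 2 * b),
         n_200_300 = sum(t >= 2 * b),
         timing_variance = v)
}
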