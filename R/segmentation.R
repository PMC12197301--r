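# Event trimming: a segment opens where the amplitude envelope first reaches
# a fraction of the recording's maximum "volume" and closes at the start of
# the first silence run longer than the gap rule. Swallows consist of 1-4
# bursts whose gaps never exceed 139.5 ms, so the default gap keeps the
# bursts of one swallow inside one segment while splitting distinct events.

#' Segmentation configuration
#'
#' @param onset_threshold_fraction Fraction of the maximum envelope value
#'   that counts as "sound" (default 0.10, i.e. 10% of the maximum volume).
#' @param silence_gap_s A run of continuous sub-threshold envelope strictly
#'   longer than this terminates a segment (default 0.1395 s; sub-threshold
#'   runs up to this length do not split a segment).
#' @param envelope_frame_s Frame length of the max-absolute-amplitude
#'   envelope (default 0.010 s).
#' @param max_clip_s Standardized classifier clip length (default 3 s).
#' @param absolute_threshold Optional absolute envelope threshold; when
#'   given it replaces the relative rule (useful for recordings whose
#'   maximum is itself noise).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(onset_threshold_fraction = 0.10,
                                silence_gap_s = 0.1395,
                                envelope_frame_s = 0.010,
                                max_clip_s = 3.0,
                                absolute_threshold = NULL) {
  stopifnot(onset_threshold_fraction > 0, onset_threshold_fraction < 1,
            silence_gap_s > 0, envelope_frame_s > 0, max_clip_s > 0)
  structure(list(onset_threshold_fraction = onset_threshold_fraction,
                 silence_gap_s = silence_gap_s,
                 envelope_frame_s = envelope_frame_s,
                 max_clip_s = max_clip_s,
                 absolute_threshold = absolute_threshold),
            class = "segmentation_config")
}

#' Framed amplitude envelope
#'
#' "Volume" is implemented as the per-frame maximum of the absolute
#' amplitude: simple, monotone in loudness, and with 10 ms frames the
#' quantization error is small against the 139.5 ms gap rule.
#'
#' @param clip An [audio_clip()]; must be non-empty.
#' @param frame_s Frame length in seconds.
#' @return A tibble with `frame`, `time_s` (frame start) and `envelope`;
#'   `ceiling(duration / frame_s)` rows.
#' @export
amplitude_envelope <- function(clip, frame_s = 0.010) {
  stopifnot(inherits(clip, "audio_clip"), frame_s > 0)
  if (!length(clip$samples)) {
    abort("Cannot compute the envelope of an empty clip.",
          class = "salivaflow_empty_clip")
  }
  frame_n <- max(1L, as.integer(round(frame_s * clip$sample_rate_hz)))
  n <- length(clip$samples)
  n_frames <- ceiling(n / frame_n)
  a <- c(abs(clip$samples), numeric(n_frames * frame_n - n))
  m <- matrix(a, nrow = frame_n)
  env <- as.numeric(do.call(pmax, asplit(m, 1)))
  tibble(frame = seq_len(n_frames),
         time_s = (seq_len(n_frames) - 1L) * frame_n / clip$sample_rate_hz,
         envelope = env)
}

#' Detect candidate sound segments
#'
#' A segment opens at the first frame whose envelope reaches the threshold
#' (by default 10% of the recording's maximum envelope) and closes at the
#' start of the first run of consecutive sub-threshold frames lasting
#' strictly longer than `silence_gap_s`. Sub-threshold runs of at most the
#' gap length do not split a segment, so the 1-4 bursts of one swallow stay
#' together. A segment still open at the end of the recording is closed at
#' the final sample. An all-silent clip yields zero segments.
#'
#' @param clip An [audio_clip()]; must be non-empty.
#' @param config A [segmentation_config()].
#' @return A tibble with one row per segment: `segment`, `start_s`, `end_s`,
#'   `duration_s` — sorted by `start_s` and non-overlapping.
#' @examples
#' sr <- 8000
#' x <- numeric(2 * sr)
#' x[1:400] <- runif(400, -1, 1)          # burst at t = 0
#' x[sr + 1:400] <- runif(400, -1, 1)     # burst at t = 1
#' detect_segments(audio_clip(x, sr))
#' @export
detect_segments <- function(clip, config = segmentation_config()) {
  stopifnot(inherits(clip, "audio_clip"), inherits(config, "segmentation_config"))
  env <- amplitude_envelope(clip, config$envelope_frame_s)
  frame_n <- max(1L, as.integer(round(config$envelope_frame_s *
                                        clip$sample_rate_hz)))
  frame_s_eff <- frame_n / clip$sample_rate_hz
  thr <- if (!is.null(config$absolute_threshold)) {
    config$absolute_threshold
  } else {
    config$onset_threshold_fraction * max(env$envelope)
  }
  active <- env$envelope >= thr & env$envelope > 0
  if (!any(active)) {
    return(tibble(segment = integer(), start_s = numeric(),
                  end_s = numeric(), duration_s = numeric()))
  }
  # A silence run terminates a segment when its duration exceeds the gap:
  # run length in frames must be strictly greater than gap_frames.
  gap_frames <- floor(config$silence_gap_s / frame_s_eff + 1e-9)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # Treat short inactive runs (<= gap_frames) between active runs as active
  # for the purpose of grouping; leading/trailing silence always splits.
  bridge <- r$values
  inner <- which(!r$values)
  inner <- inner[inner > 1 & inner < length(r$values)]
  bridge[inner[r$lengths[inner] <= gap_frames]] <- TRUE
  grp <- rle(bridge)
  g_ends <- cumsum(grp$lengths)
  g_starts <- g_ends - grp$lengths + 1L
  seg <- which(grp$values)
  out <- purrr::map(seg, function(i) {
    f0 <- starts[g_starts[i]]       # first active frame of the group
    f1 <- ends[g_ends[i]]           # last frame of the group
    # The group may end with a short inactive run only if it is the last run
    # overall; close at the last *active* frame's end ("the moment silence
    # began").
    runs <- g_starts[i]:g_ends[i]
    last_active_run <- max(runs[r$values[runs]])
    f1 <- ends[last_active_run]
    c(f0, f1)
  })
  start_s <- map_dbl(out, ~ (.x[1] - 1L) * frame_s_eff)
  end_s <- map_dbl(out, ~ min(.x[2] * frame_s_eff, clip_duration(clip)))
  tibble(segment = seq_along(out),
         start_s = start_s,
         end_s = end_s,
         duration_s = end_s - start_s)
}

#' Extract a segment's audio from its recording
#'
#' @param clip The full-recording [audio_clip()].
#' @param start_s,end_s Segment boundaries in seconds.
#' @return An [audio_clip()] slice.
#' @export
extract_segment <- function(clip, start_s, end_s) {
  stopifnot(inherits(clip, "audio_clip"), start_s >= 0, end_s > start_s)
  sr <- clip$sample_rate_hz
  i0 <- max(1L, as.integer(floor(start_s * sr)) + 1L)
  i1 <- min(length(clip$samples), as.integer(ceiling(end_s * sr)))
  out <- clip
  out$samples <- clip$samples[i0:i1]
  out
}

#' Standardize a segment to a fixed classifier clip length
#'
#' Shorter segments are zero-padded at the tail (preserving onset
#' alignment, which both spectrogram front-ends see); longer segments are
#' truncated at the tail.
#'
#' @param segment An [audio_clip()] (a trimmed segment); must be non-empty.
#' @param target_s Target duration in seconds (default 3).
#' @param sample_rate_hz Output rate; defaults to the segment's rate.
#' @return An [audio_clip()] of exactly `round(target_s * sample_rate_hz)`
#'   samples.
#' @export
standardize_clip <- function(segment, target_s = 3.0,
                             sample_rate_hz = segment$sample_rate_hz) {
  stopifnot(inherits(segment, "audio_clip"), target_s > 0)
  if (!length(segment$samples)) {
    abort("Cannot standardize an empty segment.",
          class = "salivaflow_empty_clip")
  }
  if (sample_rate_hz != segment$sample_rate_hz) {
    abort("standardize_clip does not resample; rates must match.",
          class = "salivaflow_bad_rate")
  }
  n_target <- as.integer(round(target_s * sample_rate_hz))
  x <- segment$samples
  x <- if (length(x) >= n_target) x[seq_len(n_target)] else c(x, numeric(n_target - length(x)))
  out <- segment
  out$samples <- x
  out
}
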