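#' Construct an audio clip
#'
#' An `audio_clip` is the container every stage of the pipeline consumes: a
#' mono waveform of dimensionless PCM amplitudes in \[-1, 1\] together with
#' its sample rate. All amplitude thresholds downstream are relative (a
#' fraction of the recording's own maximum), so absolute gain carries no
#' information and clips may be rescaled freely.
#'
#' @param samples Numeric vector of finite sample amplitudes.
#' @param sample_rate_hz Positive integer sample rate; 44100 is the rate of
#'   the throat microphone the pipeline was designed around. Other rates are
#'   accepted with a warning since all window and hop lengths are derived
#'   from the rate, not hard-coded.
#' @return An object of class `audio_clip` with fields `samples` and
#'   `sample_rate_hz`.
#' @examples
#' clip <- audio_clip(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' clip_duration(clip)
#' @export
audio_clip <- function(samples, sample_rate_hz = 44100) {
  samples <- as.numeric(samples)
  if (length(sample_rate_hz) != 1 || !is.finite(sample_rate_hz) ||
      sample_rate_hz <= 0) {
    abort("`sample_rate_hz` must be a single positive number.",
          class = "salivaflow_bad_rate")
  }
  if (length(samples) && !all(is.finite(samples))) {
    abort("All samples must be finite.", class = "salivaflow_bad_samples")
  }
  if (sample_rate_hz != 44100) {
    warn(sprintf("sample rate %g Hz differs from the 44100 Hz the pipeline was designed for; window lengths scale accordingly",
                 sample_rate_hz),
         class = "salivaflow_rate_warning")
  }
  structure(list(samples = samples,
                 sample_rate_hz = as.integer(round(sample_rate_hz))),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip: %d samples @ %d Hz = %.3f s, peak %.3g>\n",
              length(x$samples), x$sample_rate_hz, clip_duration(x),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of a clip in seconds
#' @param clip An `audio_clip`.
#' @return Duration in seconds (`length(samples) / sample_rate_hz`).
#' @export
clip_duration <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  length(clip$samples) / clip$sample_rate_hz
}

#' Peak-normalize a clip
#'
#' Rescales so the maximum absolute amplitude is exactly 1. An all-zero clip
#' is returned unchanged (there is nothing to normalize against). Because
#' every detection threshold in the pipeline is a fraction of the
#' recording's own maximum, peak normalization never changes a downstream
#' result; it exists to make clips comparable for display and storage.
#'
#' @param clip An `audio_clip`; must be non-empty.
#' @return An `audio_clip` with `max(abs(samples)) == 1` (or all zeros).
#' @export
peak_normalize <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!length(clip$samples)) {
    abort("Cannot normalize an empty clip.", class = "salivaflow_empty_clip")
  }
  peak <- max(abs(clip$samples))
  if (peak == 0) return(clip)
  out <- clip
  out$samples <- clip$samples / peak
  out
}
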