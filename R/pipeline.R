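# End-to-end wiring: WAV recording -> segments -> classification ->
# event series -> five features -> estimated grams per 30 s, with all
# stage defaults collected in one serializable configuration document.

#' Pipeline configuration
#'
#' All stage defaults in one round-trippable document (YAML on disk).
#'
#' @param segmentation A [segmentation_config()] (stored as plain fields).
#' @param window_s Observation window for the event series (default 300).
#' @param suppress_window_s Consecutive-swallow suppression window.
#' @param alpha Ridge penalty.
#' @param method Classification method, 1 or 2.
#' @param seed Seed applied to every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = segmentation_config(),
                            window_s = 300, suppress_window_s = 2.0,
                            alpha = 10, method = 2, seed = 1L) {
  structure(list(onset_threshold_fraction = segmentation$onset_threshold_fraction,
                 silence_gap_s = segmentation$silence_gap_s,
                 envelope_frame_s = segmentation$envelope_frame_s,
                 max_clip_s = segmentation$max_clip_s,
                 window_s = window_s,
                 suppress_window_s = suppress_window_s,
                 alpha = alpha, method = as.integer(method),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns the configuration; the writer
#'   returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg$method <- as.integer(cfg$method)
  cfg
}

#' Run the full estimation pipeline on a recording
#'
#' Segments the recording, standardizes each segment to the classifier
#' clip length, classifies swallow vs non-swallow, suppresses consecutive
#' detections, extracts the five timing features, and predicts grams of
#' saliva secreted per 30 s with the fitted ridge model. Intermediate
#' tables are written to `out_dir` when given (segments.csv, events.csv,
#' features.csv, prediction.json).
#'
#' @param recording An [audio_clip()] or path to a WAV file.
#' @param classifier A trained `swallow_classifier`.
#' @param estimator A fitted `ridge_model`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for intermediate artifacts.
#' @return List with `segments`, `events`, `features`, `predicted_g` and
#'   the per-segment `classification` tibble.
#' @export
run_pipeline <- function(recording, classifier, estimator,
                         config = pipeline_config(), out_dir = NULL) {
  clip <- if (inherits(recording, "audio_clip")) recording else
    read_wav(recording)
  if (!inherits(classifier, "swallow_classifier") ||
      !isTRUE(classifier$trained)) {
    abort("`classifier` must be a trained swallow_classifier.",
          class = "salivaflow_untrained")
  }
  if (!inherits(estimator, "ridge_model")) {
    abort("`estimator` must be a fitted ridge_model.",
          class = "salivaflow_unfitted")
  }
  seg_cfg <- segmentation_config(
    onset_threshold_fraction = config$onset_threshold_fraction,
    silence_gap_s = config$silence_gap_s,
    envelope_frame_s = config$envelope_frame_s,
    max_clip_s = config$max_clip_s)
  segments <- detect_segments(clip, seg_cfg)
  classification <- if (nrow(segments)) {
    clips <- map(seq_len(nrow(segments)), function(i) {
      standardize_clip(extract_segment(clip, segments$start_s[i],
                                       segments$end_s[i]),
                       target_s = seg_cfg$max_clip_s)
    })
    dplyr::bind_cols(segments, predict(classifier, clips))
  } else {
    dplyr::mutate(segments, prob = numeric(0), is_swallow = logical(0))
  }
  events <- segments_to_events(segments,
                               labels = classification$is_swallow,
                               window_s = config$window_s)
  events <- deduplicate_events(events, config$suppress_window_s)
  features <- extract_features(events, config$window_s)
  predicted_g <- predict_saliva(estimator, features)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(classification, file.path(out_dir, "segments.csv"),
                     row.names = FALSE)
    utils::write.csv(events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(predicted_saliva_g_per_30s = predicted_g),
                         file.path(out_dir, "prediction.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(segments = segments, classification = classification,
       events = events, features = features, predicted_g = predicted_g)
}
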