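# Binary swallow / non-swallow classification. Method 1 feeds a Hann STFT
# spectrogram (10.1 ms window, 5.05 ms hop) to a CNN with four convolution
# layers, four pooling layers and three fully-connected layers. Method 2
# feeds 224x224x3 complex-Gaussian (gaus5) scalogram images to a compact
# convolutional backbone with a replaceable binary head. Both use ReLU
# activations, Adam, and binary cross-entropy.

#' Training configuration
#'
#' @param epochs Number of passes over the training set (default 30).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Seed that fully determines weight initialization and data
#'   order, hence the trained model.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 30, batch_size = 32,
                         learning_rate = 1e-3, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

#' Build the Method 1 classifier (STFT spectrogram + CNN)
#'
#' Exactly four 3x3 convolution layers (channel widths `channels`), four
#' 2x2 max-pooling layers, and three fully-connected layers (widths
#' `fc_units`, then a single sigmoid unit). The STFT magnitude is
#' log-compressed and bilinearly resized to `input_shape` before entering
#' the network; the resolution is a package choice, not dictated by the
#' transform.
#'
#' @param input_shape Height, width, channels of the network input
#'   (default c(48, 48, 1)); height and width must be divisible by 16 so
#'   four pooling stages fit.
#' @param channels Convolution channel widths, length 4.
#' @param fc_units Widths of the first two fully-connected layers.
#' @param seed Weight-initialization seed.
#' @return A `swallow_classifier` object.
#' @export
build_method1 <- function(input_shape = c(48, 48, 1),
                          channels = c(16, 32, 64, 128),
                          fc_units = c(256, 64), seed = 1L) {
  stopifnot(length(input_shape) == 3, length(channels) == 4,
            length(fc_units) == 2)
  if (input_shape[1] %% 16 != 0 || input_shape[2] %% 16 != 0 ||
      input_shape[1] < 16 || input_shape[2] < 16) {
    abort("Method 1 input height/width must be positive multiples of 16 (four 2x2 pooling stages).",
          class = "salivaflow_bad_input_shape")
  }
  spec <- list()
  for (ch in channels) {
    spec <- c(spec, list(list(type = "conv", channels = ch),
                         list(type = "pool")))
  }
  spec <- c(spec, list(list(type = "dense", units = fc_units[1]),
                       list(type = "dense", units = fc_units[2]),
                       list(type = "dense", units = 1)))
  structure(list(nn = nn_build(input_shape, spec, seed = seed),
                 method = 1L, front_end = "stft",
                 input_shape = input_shape, trained = FALSE),
            class = "swallow_classifier")
}

#' Build the Method 2 classifier (CWT scalogram image + backbone)
#'
#' Consumes 224x224x3 scalogram images. The only backbone that ships with
#' the package is `"small_cnn_fallback"`: a fixed grayscale average-pooling
#' stem (224 -> 32) followed by two convolution/pooling stages and a
#' two-layer binary head, so it builds and trains with no downloaded
#' weights. With `freeze = TRUE` the convolutional backbone is frozen and
#' only the head is trained. Requesting `"densenet121"` raises an error:
#' pretrained DenseNet weights are not bundled with the package.
#'
#' @param backbone `"small_cnn_fallback"` or `"densenet121"`.
#' @param freeze Train only the fully-connected head (default FALSE).
#' @param seed Weight-initialization seed.
#' @param image_size Input image side (default 224).
#' @param stem_factor Average-pooling factor of the stem (default 7).
#' @return A `swallow_classifier` object.
#' @export
build_method2 <- function(backbone = "small_cnn_fallback", freeze = FALSE,
                          seed = 1L, image_size = 224, stem_factor = 7) {
  if (identical(backbone, "densenet121")) {
    abort("Pretrained DenseNet121 weights are not bundled and cannot be downloaded here; use backbone = 'small_cnn_fallback'.",
          class = "salivaflow_backbone_unavailable")
  }
  if (!identical(backbone, "small_cnn_fallback")) {
    abort(sprintf("Unknown backbone '%s'.", backbone),
          class = "salivaflow_unknown_backbone")
  }
  side <- image_size %/% stem_factor
  stopifnot(side %% 4 == 0, side >= 8)
  spec <- list(list(type = "conv", channels = 16), list(type = "pool"),
               list(type = "conv", channels = 32), list(type = "pool"),
               list(type = "dense", units = 64),
               list(type = "dense", units = 1))
  nn <- nn_build(c(side, side, 1), spec, seed = seed)
  if (freeze) {
    for (li in seq_along(nn$layers)) {
      if (nn$layers[[li]]$type == "conv") nn$layers[[li]]$trainable <- FALSE
    }
  }
  structure(list(nn = nn, method = 2L, front_end = "cwt",
                 backbone = backbone, freeze = freeze,
                 image_size = image_size, stem_factor = stem_factor,
                 input_shape = c(image_size, image_size, 3), trained = FALSE),
            class = "swallow_classifier")
}

#' @export
print.swallow_classifier <- function(x, ...) {
  counts <- nn_layer_counts(x$nn)
  cat(sprintf("<swallow_classifier: method %d (%s front-end), %d conv / %d pool / %d FC layers, %s params%s>\n",
              x$method, x$front_end, counts["conv"], counts["pool"],
              counts["dense"], format(nn_n_params(x$nn), big.mark = ","),
              if (isTRUE(x$trained)) ", trained" else ""))
  invisible(x)
}

#' Layer census of a classifier
#'
#' @param model A `swallow_classifier`.
#' @return Named integer vector with `conv`, `pool`, `dense` counts.
#' @export
layer_counts <- function(model) {
  stopifnot(inherits(model, "swallow_classifier"))
  nn_layer_counts(model$nn)
}

#' Parameter counts of a classifier
#'
#' @param model A `swallow_classifier`.
#' @param trainable_only Count only trainable parameters.
#' @return Number of parameters.
#' @export
n_parameters <- function(model, trainable_only = FALSE) {
  stopifnot(inherits(model, "swallow_classifier"))
  nn_n_params(model$nn, trainable_only = trainable_only)
}

# Grayscale block-average downsampling of an image array (stem of the
# fallback backbone).
stem_downsample <- function(img, factor) {
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  side <- nrow(gray) %/% factor
  grp <- rep(seq_len(side), each = factor)
  pooled <- t(rowsum(t(rowsum(gray[seq_len(side * factor),
                                   seq_len(side * factor)], grp)), grp))
  array(pooled / factor^2, c(side, side, 1))
}

# Clip -> network-ready array for a given classifier.
classifier_preprocess <- function(model, clip) {
  stopifnot(inherits(clip, "audio_clip"))
  if (model$front_end == "stft") {
    sp <- stft_spectrogram(clip)
    img <- to_image(sp$magnitude, size = model$input_shape[1],
                    log_compress = TRUE)
    array(img[, , 1], model$input_shape)
  } else {
    dec <- decimate_clip(clip, target_hz = 8820)
    sc <- cwt_scalogram(dec)
    img <- to_image(sc$magnitude, size = model$image_size,
                    log_compress = TRUE)
    stem_downsample(img, model$stem_factor)
  }
}

# Anti-aliased integer-factor decimation; swallow-band content lives below
# 3 kHz so classification does not need the full 44.1 kHz rate.
decimate_clip <- function(clip, target_hz = 8820) {
  q <- max(1L, as.integer(round(clip$sample_rate_hz / target_hz)))
  if (q == 1L) return(clip)
  out <- clip
  out$samples <- as.numeric(signal::decimate(clip$samples, q))
  out$sample_rate_hz <- as.integer(round(clip$sample_rate_hz / q))
  out
}

#' Train a swallow classifier
#'
#' Runs seeded Adam / binary cross-entropy training. The front-end
#' features of every clip are computed once up front.
#'
#' @param model A `swallow_classifier` from [build_method1()] or
#'   [build_method2()].
#' @param dataset A labeled-clip tibble with list-column `clip` and logical
#'   `binary_label` (see [generate_labeled_dataset()]); must contain both
#'   classes.
#' @param config A [train_config()].
#' @param .images Optional precomputed list of front-end arrays aligned
#'   with `dataset` (used to avoid recomputation across folds).
#' @return The trained model, with a `history` tibble (epoch, loss,
#'   accuracy) attached.
#' @export
train_classifier <- function(model, dataset, config = train_config(),
                             .images = NULL) {
  stopifnot(inherits(model, "swallow_classifier"),
            is.data.frame(dataset), "binary_label" %in% names(dataset))
  y <- as.integer(dataset$binary_label)
  if (length(unique(y)) < 2) {
    abort("Training data must contain both classes.",
          class = "salivaflow_single_class")
  }
  images <- .images %||% map(dataset$clip, ~ classifier_preprocess(model, .x))
  fit <- nn_train(model$nn, images, y,
                  epochs = config$epochs, batch_size = config$batch_size,
                  learning_rate = config$learning_rate, seed = config$seed)
  model$nn <- fit$model
  model$history <- fit$history
  model$trained <- TRUE
  model
}

#' Classify clips as swallow / non-swallow
#'
#' @param object A trained `swallow_classifier`.
#' @param clips An [audio_clip()] or list of clips (or a labeled-clip
#'   tibble, whose `clip` column is used).
#' @param threshold Decision threshold on the swallow probability
#'   (default 0.5).
#' @param ... Unused.
#' @return A tibble with `prob` (P(swallow)) and logical `is_swallow`.
#' @export
predict.swallow_classifier <- function(object, clips, threshold = 0.5, ...) {
  if (!isTRUE(object$trained)) {
    abort("Model has not been trained.", class = "salivaflow_untrained")
  }
  if (inherits(clips, "audio_clip")) clips <- list(clips)
  if (is.data.frame(clips)) clips <- clips$clip
  probs <- map_dbl(clips, function(cl) {
    nn_forward(object$nn, classifier_preprocess(object, cl))$prob
  })
  tibble(prob = probs, is_swallow = probs >= threshold)
}

#' Stratified (or subject-grouped) cross-validation folds
#'
#' Stratification shuffles within each class with the given seed and deals
#' indices round-robin, so per-fold class counts differ by at most one
#' item from exact proportionality.
#'
#' @param labels Class label per item (any vector).
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @param groups Optional grouping vector (e.g. subject ids); when given,
#'   whole groups are dealt to folds instead of items.
#' @return Integer fold assignment (1..k) per item.
#' @export
make_stratified_folds <- function(labels, k = 5, seed = 1L, groups = NULL) {
  stopifnot(k >= 2, length(labels) >= k)
  set.seed(seed)
  fold <- integer(length(labels))
  if (!is.null(groups)) {
    g <- unique(groups)
    g <- sample(g)
    assign <- setNames(rep_len(seq_len(k), length(g)), g)
    fold <- unname(assign[as.character(groups)])
  } else {
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      ix <- sample(ix)
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
  }
  fold
}

#' k-fold cross-validated accuracy of a classification method
#'
#' Builds and trains a fresh model per fold (stratified by binary class,
#' seeded shuffle), tests on the held-out fold, and reports per-fold and
#' mean accuracy. Every item is tested exactly once. Front-end features
#' are computed once and shared across folds.
#'
#' @param dataset Labeled-clip tibble (see [generate_labeled_dataset()]).
#' @param k Number of folds (default 5).
#' @param method 1 (STFT + CNN) or 2 (CWT + backbone).
#' @param config A [train_config()]; the per-fold training seed is
#'   `config$seed + fold`.
#' @param seed Fold-assignment seed.
#' @param group_by_subject Deal whole subjects to folds instead of
#'   stratifying by class (cross-subject evaluation).
#' @return A `fold_report`: list with `per_fold` tibble (fold, n_test,
#'   accuracy) and `mean_accuracy`.
#' @export
kfold_evaluate <- function(dataset, k = 5, method = 1,
                           config = train_config(), seed = 1L,
                           group_by_subject = FALSE) {
  stopifnot(k >= 2, nrow(dataset) >= k)
  proto <- if (method == 1) build_method1() else build_method2()
  images <- map(dataset$clip, ~ classifier_preprocess(proto, .x))
  fold <- make_stratified_folds(
    dataset$binary_label, k = k, seed = seed,
    groups = if (group_by_subject) dataset$subject_id)
  y <- as.integer(dataset$binary_label)
  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- which(fold != f)
    te <- which(fold == f)
    model <- if (method == 1) {
      build_method1(seed = config$seed + f)
    } else {
      build_method2(seed = config$seed + f)
    }
    cfg <- config
    cfg$seed <- config$seed + f
    model <- train_classifier(model, dataset[tr, ], cfg,
                              .images = images[tr])
    probs <- map_dbl(te, ~ nn_forward(model$nn, images[[.x]])$prob)
    tibble(fold = f, n_test = length(te),
           accuracy = mean((probs >= 0.5) == (y[te] == 1)))
  })
  structure(list(per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy),
                 k = k, method = method),
            class = "fold_report")
}

#' @export
print.fold_report <- function(x, ...) {
  cat(sprintf("<fold_report: method %d, %d folds, mean accuracy %.4f>\n",
              x$method, x$k, x$mean_accuracy))
  print(x$per_fold)
  invisible(x)
}

#' @export
tidy.fold_report <- function(x, ...) x$per_fold

#' @export
glance.fold_report <- function(x, ...) {
  tibble(k = x$k, method = x$method, mean_accuracy = x$mean_accuracy,
         sd_accuracy = sd(x$per_fold$accuracy))
}

#' Accuracy and confusion counts on a held-out labeled set
#'
#' @param model A trained `swallow_classifier`.
#' @param dataset Labeled-clip tibble; must be non-empty.
#' @return List with `accuracy` and a `confusion` tibble
#'   (`truth`, `predicted`, `n`) whose counts sum to `nrow(dataset)`.
#' @export
holdout_evaluate <- function(model, dataset) {
  stopifnot(nrow(dataset) > 0)
  pred <- predict(model, dataset)
  truth <- dataset$binary_label
  confusion <- tibble(truth = truth, predicted = pred$is_swallow) |>
    dplyr::count(.data$truth, .data$predicted, name = "n")
  list(accuracy = mean(pred$is_swallow == truth), confusion = confusion)
}
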