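# Ridge regression from the five swallow-timing features to grams of
# saliva secreted per 30 s, and the evaluation suite: leave-one-out
# cross-validation, Pearson r and MAE, the moving-average MAE curve
# (window 0.05 g, overlap 0.025 g), the sorted half-split MAE, and the
# within-subject versus overall variability of the ground truth.

feature_columns <- c("n_total", "n_0_100", "n_100_200", "n_200_300",
                     "timing_variance")

#' Fit ridge regression of saliva secretion on swallow-timing features
#'
#' Closed-form ridge solution on standardized features (zero mean, unit
#' variance computed from the training data; the penalty `alpha` applies
#' on that scale) with an unpenalized intercept. Features with zero
#' variance are centered but not scaled.
#'
#' @param trials Tibble with the feature columns `n_total`, `n_0_100`,
#'   `n_100_200`, `n_200_300`, `timing_variance` and the target
#'   `saliva_g`; at least 2 rows.
#' @param alpha Ridge penalty (default 10).
#' @param features Feature column names (defaults to the five above).
#' @return A `ridge_model` with `coefficients` (on the standardized
#'   scale), `intercept`, `alpha`, and the stored standardization
#'   constants `feature_means` and `feature_scales`.
#' @export
fit_ridge <- function(trials, alpha = 10, features = feature_columns) {
  stopifnot(is.data.frame(trials), alpha >= 0,
            all(c(features, "saliva_g") %in% names(trials)))
  if (nrow(trials) < 2) {
    abort("Need at least 2 trials to fit.", class = "salivaflow_too_few")
  }
  X <- as.matrix(trials[features])
  y <- trials$saliva_g
  mu <- colMeans(X)
  sc <- apply(X, 2, sd)
  sc[sc == 0 | !is.finite(sc)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sc, "/")
  yc <- y - mean(y)
  A <- crossprod(Z) + diag(alpha, ncol(Z))
  beta <- drop(solve(A, crossprod(Z, yc)))
  structure(list(coefficients = setNames(beta, features),
                 intercept = mean(y), alpha = alpha,
                 feature_means = setNames(mu, features),
                 feature_scales = setNames(sc, features),
                 features = features, n = nrow(trials)),
            class = "ridge_model")
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("<ridge_model: alpha = %g, n = %d, intercept = %.4g>\n",
              x$alpha, x$n, x$intercept))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.ridge_model <- function(x, ...) {
  tibble(term = c("(Intercept)", x$features),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @export
glance.ridge_model <- function(x, ...) {
  tibble(alpha = x$alpha, n = x$n,
         coef_l2 = sqrt(sum(x$coefficients^2)))
}

#' Predict grams of saliva secreted per 30 s
#'
#' @param model A fitted `ridge_model`.
#' @param features One or more feature rows (tibble with the model's
#'   feature columns).
#' @param clip_at_zero Clip negative predictions to 0 (default FALSE; the
#'   fitted relationship is used as-is).
#' @return Numeric vector of predicted grams per 30 s.
#' @export
predict_saliva <- function(model, features, clip_at_zero = FALSE) {
  stopifnot(inherits(model, "ridge_model"))
  X <- as.matrix(features[model$features])
  Z <- sweep(sweep(X, 2, model$feature_means), 2, model$feature_scales, "/")
  p <- model$intercept + drop(Z %*% model$coefficients)
  if (clip_at_zero) p <- pmax(0, p)
  unname(p)
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  predict_saliva(object, newdata, ...)
}

#' Leave-one-out cross-validated predictions
#'
#' Each trial is predicted by a model fitted on all other trials; with n
#' trials the fit is repeated n times. Predictions depend only on the
#' data, not on row order.
#'
#' @inheritParams fit_ridge
#' @return `trials` with a `.pred` column appended.
#' @export
loocv_ridge <- function(trials, alpha = 10, features = feature_columns) {
  n <- nrow(trials)
  if (n < 3) {
    abort("Need at least 3 trials for leave-one-out.",
          class = "salivaflow_too_few")
  }
  preds <- map_dbl(seq_len(n), function(i) {
    m <- fit_ridge(trials[-i, ], alpha = alpha, features = features)
    predict_saliva(m, trials[i, ])
  })
  dplyr::mutate(trials, .pred = preds)
}

#' Pearson correlation and mean absolute error
#'
#' MAE is `mean(abs(pred - truth))` in grams per 30 s; r is the Pearson
#' correlation between predictions and measurements. If either vector has
#' zero variance r is undefined and reported as NA with a warning.
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return One-row tibble with `r`, `mae`, `n`.
#' @export
compute_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  mae <- mean(abs(pred - truth))
  r <- if (length(pred) >= 2 && sd(pred) > 0 && sd(truth) > 0) {
    cor(pred, truth)
  } else {
    warn("Correlation undefined (zero variance); reporting NA.",
         class = "salivaflow_r_undefined")
    NA_real_
  }
  tibble(r = r, mae = mae, n = length(pred))
}

#' Moving-average MAE over the measured secretion range
#'
#' Bins the trials by measured grams with a sliding window (default width
#' 0.05 g, overlap 0.025 g, i.e. the grid steps by 0.025 g starting at
#' the multiple of the step just below the smallest measurement) and
#' reports the MAE of the trials whose measurement falls in each window.
#' Empty windows are omitted.
#'
#' @param pred,truth Equal-length numeric vectors (non-empty).
#' @param window_g Window width in grams (default 0.05).
#' @param overlap_g Overlap between consecutive windows (default 0.025);
#'   must be smaller than `window_g`.
#' @return Tibble with `bin_center_g`, `mae_g`, `n` per non-empty window.
#' @export
moving_average_mae <- function(pred, truth, window_g = 0.05,
                               overlap_g = 0.025) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  if (overlap_g >= window_g) {
    abort("`overlap_g` must be smaller than `window_g`.",
          class = "salivaflow_bad_window")
  }
  step <- window_g - overlap_g
  starts <- seq(floor(min(truth) / step) * step, max(truth), by = step)
  purrr::map_dfr(starts, function(s) {
    in_bin <- truth >= s & truth < s + window_g
    if (!any(in_bin)) return(NULL)
    tibble(bin_center_g = s + window_g / 2,
           mae_g = mean(abs(pred[in_bin] - truth[in_bin])),
           n = sum(in_bin))
  })
}

#' MAE of the low and high halves of the measured range
#'
#' Trials are sorted by measured secretion and split in two; with an odd
#' number of trials the median trial joins the lower half. Mirrors the
#' low-secretion versus high-secretion error comparison of the
#' evaluation protocol.
#'
#' @param pred,truth Equal-length numeric vectors, n >= 2.
#' @return Tibble with `half` ("low", "high"), `mae_g`, `n`.
#' @export
split_half_mae <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2)
  ord <- order(truth)
  n <- length(truth)
  n_low <- ceiling(n / 2)
  lo <- ord[seq_len(n_low)]
  hi <- ord[(n_low + 1):n]
  tibble(half = c("low", "high"),
         mae_g = c(mean(abs(pred[lo] - truth[lo])),
                   mean(abs(pred[hi] - truth[hi]))),
         n = c(length(lo), length(hi)))
}

#' Within-subject and overall variability of measured secretion
#'
#' The within-subject figure is the mean over subjects of the per-subject
#' sample standard deviation (divisor n-1); the overall figure is the
#' sample SD over all trials. Subjects with a single trial cannot
#' contribute a within-subject SD and are excluded with a warning.
#'
#' @param trials Tibble with `subject_id` and `saliva_g`.
#' @return One-row tibble with `within_subject_sd`, `overall_sd`,
#'   `n_subjects`.
#' @export
subject_variability <- function(trials) {
  stopifnot(all(c("subject_id", "saliva_g") %in% names(trials)))
  per <- trials |>
    group_by(.data$subject_id) |>
    summarise(sd = sd(.data$saliva_g), n = n(), .groups = "drop")
  singles <- per$n < 2
  if (any(singles)) {
    warn(sprintf("%d subject(s) with a single trial excluded from the within-subject SD.",
                 sum(singles)), class = "salivaflow_single_trial_subject")
  }
  tibble(within_subject_sd = mean(per$sd[!singles]),
         overall_sd = sd(trials$saliva_g),
         n_subjects = sum(!singles))
}

#' Full estimator evaluation
#'
#' Runs leave-one-out ridge over the trials and assembles the complete
#' report: pooled Pearson r and MAE, the moving-average MAE curve, the
#' sorted half-split MAEs, and the subject variability of the ground
#' truth.
#'
#' @inheritParams fit_ridge
#' @param window_g,overlap_g Moving-average MAE parameters.
#' @return A `saliva_eval` object: list with `trials` (including `.pred`),
#'   `metrics`, `mae_curve`, `half_mae`, `variability`, `alpha`.
#' @export
evaluate_estimator <- function(trials, alpha = 10, window_g = 0.05,
                               overlap_g = 0.025) {
  fitted <- loocv_ridge(trials, alpha = alpha)
  metrics <- compute_metrics(fitted$.pred, fitted$saliva_g)
  structure(list(trials = fitted,
                 metrics = metrics,
                 mae_curve = moving_average_mae(fitted$.pred,
                                                fitted$saliva_g,
                                                window_g, overlap_g),
                 half_mae = split_half_mae(fitted$.pred, fitted$saliva_g),
                 variability = if ("subject_id" %in% names(trials))
                   subject_variability(trials) else NULL,
                 alpha = alpha),
            class = "saliva_eval")
}

#' @export
print.saliva_eval <- function(x, ...) {
  cat(sprintf("<saliva_eval: n = %d trials, alpha = %g>\n",
              nrow(x$trials), x$alpha))
  cat(sprintf("  r = %.3f, MAE = %.4f g/30s\n", x$metrics$r, x$metrics$mae))
  cat(sprintf("  half-split MAE: low %.4f g, high %.4f g\n",
              x$half_mae$mae_g[1], x$half_mae$mae_g[2]))
  if (!is.null(x$variability)) {
    cat(sprintf("  SD: within-subject %.4f g, overall %.4f g\n",
                x$variability$within_subject_sd, x$variability$overall_sd))
  }
  invisible(x)
}

#' @export
glance.saliva_eval <- function(x, ...) {
  out <- tibble(r = x$metrics$r, mae = x$metrics$mae, n = x$metrics$n,
                mae_low_half = x$half_mae$mae_g[1],
                mae_high_half = x$half_mae$mae_g[2], alpha = x$alpha)
  if (!is.null(x$variability)) {
    out$within_subject_sd <- x$variability$within_subject_sd
    out$overall_sd <- x$variability$overall_sd
  }
  out
}

#' @export
tidy.saliva_eval <- function(x, ...) x$trials
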