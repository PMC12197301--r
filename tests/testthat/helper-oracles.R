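# Independent oracles and fixture builders shared across the test files.
# These deliberately re-derive the expected behaviour with naive code paths
# (explicit state machines, per-element loops) so they do not share logic
# with the vectorized implementations they check.

# Build a recording from a known burst layout: bursts of uniform noise at
# given (start_s, dur_s, amp), over an optional sub-threshold noise floor.
make_layout_clip <- function(bursts, duration_s = 4, sr = 44100,
                             floor_amp = 0.02) {
  n <- as.integer(round(duration_s * sr))
  x <- runif(n, -floor_amp, floor_amp)
  for (b in seq_len(nrow(bursts))) {
    i0 <- as.integer(round(bursts$start_s[b] * sr)) + 1L
    i1 <- min(n, i0 + as.integer(round(bursts$dur_s[b] * sr)) - 1L)
    x[i0:i1] <- runif(i1 - i0 + 1L, -bursts$amp[b], bursts$amp[b])
  }
  audio_clip(x, sr)
}

# Random burst layout whose gaps stay well clear of the 139.5 ms rule
# boundary (merge gaps <= 0.12 s, split gaps >= 0.16 s), so sample-level
# and frame-level scans cannot disagree through quantization alone.
random_layout <- function(n_bursts = NULL, duration_s = 4) {
  n_bursts <- if (is.null(n_bursts)) sample(1:5, 1) else n_bursts
  start <- runif(1, 0.1, 0.4)
  rows <- list()
  for (b in seq_len(n_bursts)) {
    dur <- runif(1, 0.05, 0.4)
    rows[[b]] <- data.frame(start_s = start, dur_s = dur,
                            amp = runif(1, 0.5, 1))
    gap <- if (runif(1) < 0.5) runif(1, 0.03, 0.12) else runif(1, 0.16, 0.5)
    start <- start + dur + gap
  }
  out <- do.call(rbind, rows)
  out[out$start_s + out$dur_s < duration_s - 0.05, , drop = FALSE]
}

# Sample-granularity segmentation oracle: explicit run walk with the same
# rules (threshold = fraction of the recording max; a silence run strictly
# longer than the gap closes the segment at the moment silence began).
oracle_segments <- function(clip, threshold_frac = 0.10, gap_s = 0.1395) {
  x <- abs(clip$samples)
  sr <- clip$sample_rate_hz
  thr <- threshold_frac * max(x)
  loud <- x >= thr
  if (!any(loud)) return(data.frame(start_s = numeric(), end_s = numeric()))
  r <- rle(loud)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gap_n <- gap_s * sr
  segs <- list()
  open_start <- NA
  last_loud_end <- NA
  for (k in seq_along(r$values)) {
    if (r$values[k]) {
      if (is.na(open_start)) open_start <- starts[k]
      last_loud_end <- ends[k]
    } else if (!is.na(open_start)) {
      terminal <- k == length(r$values)
      if (terminal || r$lengths[k] > gap_n) {
        segs[[length(segs) + 1]] <- c(open_start, last_loud_end)
        open_start <- NA
      }
    }
  }
  if (!is.na(open_start)) {
    segs[[length(segs) + 1]] <- c(open_start, last_loud_end)
  }
  data.frame(start_s = vapply(segs, function(s) (s[1] - 1) / sr, 0),
             end_s = vapply(segs, function(s) s[2] / sr, 0))
}

# Greedy consecutive-swallow suppression, written as the obvious loop.
oracle_dedup <- function(times, window = 2.0) {
  kept <- numeric(0)
  for (t in times) {
    if (!length(kept) || t - kept[length(kept)] > window) kept <- c(kept, t)
  }
  kept
}

# Brute-force moving-average MAE binning.
oracle_moving_mae <- function(pred, truth, window = 0.05, overlap = 0.025) {
  step <- window - overlap
  starts <- seq(floor(min(truth) / step) * step, max(truth), by = step)
  out <- list()
  for (s in starts) {
    sel <- truth >= s & truth < s + window
    if (any(sel)) {
      out[[length(out) + 1]] <- data.frame(
        bin_center_g = s + window / 2,
        mae_g = mean(abs(pred[sel] - truth[sel])), n = sum(sel))
    }
  }
  do.call(rbind, out)
}

# Hand-rolled standardized ridge with unpenalized intercept, via the
# normal equations assembled element by element.
oracle_ridge_predict <- function(train, test_row, alpha,
                                 features = c("n_total", "n_0_100",
                                              "n_100_200", "n_200_300",
                                              "timing_variance")) {
  X <- as.matrix(train[features])
  y <- train$saliva_g
  mu <- colMeans(X)
  sc <- apply(X, 2, stats::sd)
  sc[sc == 0] <- 1
  Z <- scale(X, center = mu, scale = sc)
  b <- solve(t(Z) %*% Z + alpha * diag(ncol(Z)), t(Z) %*% (y - mean(y)))
  z <- (as.numeric(test_row[1, features]) - mu) / sc
  mean(y) + sum(z * b)
}

# Small fast labeled corpus for classifier unit tests (shorter clips keep
# the CWT front-end cheap).
tiny_corpus <- function(n_each = 6, seed = 1) {
  ds <- generate_labeled_dataset(n_swallow = n_each, n_distractor = n_each,
                                 seed = seed)
  ds
}

expect_no_condition_quietly <- function(expr) {
  expect_error(expr, NA)
}
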