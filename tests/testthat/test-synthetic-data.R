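test_that("noiseless clearance matches the closed-form event count", {
  zero <- simulate_oral_clearance(dawes_params(flow_rate_ml_per_min = 0))
  expect_equal(nrow(zero$events), 0)
  expect_true(all(zero$trajectory$volume_ml == 0.8))
  p <- dawes_params(flow_rate_ml_per_min = 0.4, vmax_ml = 1.0,
                    resid_ml = 0.2)
  sim <- simulate_oral_clearance(p, duration_s = 600)
  expect_equal(nrow(sim$events), 5)      # floor(0.4*10/0.8)
  expect_equal(sim$events$time_s, (1:5) * 120)
  set.seed(43)
  for (i in 1:20) {
    flow <- runif(1, 0.05, 2)
    gap <- runif(1, 0.2, 1)
    pp <- dawes_params(flow, vmax_ml = 1 + gap, resid_ml = 1)
    got <- nrow(simulate_oral_clearance(pp, duration_s = 300)$events)
    expect_equal(got, floor(flow * 5 / gap * (1 + 1e-9)))
  }
  expect_error(dawes_params(vmax_ml = 0.5, resid_ml = 0.8),
               class = "salivaflow_bad_dawes")
})

test_that("the default calibration yields about one swallow per minute", {
  sim <- simulate_oral_clearance(dawes_params(), duration_s = 600)
  expect_gte(nrow(sim$events), 8)       # 0.48/0.5 = 0.96 per minute
  expect_lte(nrow(sim$events), 12)
  expect_true(all(sim$trajectory$volume_ml >= 0.8 - 1e-9))
  expect_true(all(sim$trajectory$volume_ml <= 1.3 + 1e-9))
})

test_that("event counts stay deterministic per seed and grow with flow", {
  p <- dawes_params(0.5, flow_noise_cv = 0.3)
  a <- simulate_oral_clearance(p, seed = 7)$events
  b <- simulate_oral_clearance(p, seed = 7)$events
  expect_identical(a, b)
  set.seed(3)
  mean_count <- function(flow) {
    mean(vapply(1:8, function(s) {
      nrow(simulate_oral_clearance(
        dawes_params(flow, flow_noise_cv = 0.2), seed = s)$events)
    }, 0))
  }
  expect_gt(mean_count(1.2), mean_count(0.3))
})

test_that("cotton measurements are unbiased with the requested noise", {
  expect_equal(simulate_cotton_measurement(0, 0, seed = 1), 0)
  expect_equal(simulate_cotton_measurement(0.48, 0, seed = 1), 0.24)
  draws <- simulate_cotton_measurement(rep(0.48, 1e4), 0.03, seed = 2)
  expect_lt(abs(sd(draws) - 0.03) / 0.03, 0.05)
  expect_lt(abs(mean(draws) - 0.24), 0.002)
  expect_true(all(draws >= 0))
})

test_that("synthetic swallows segment as exactly one event of the right length", {
  for (s in 1:8) {
    clip <- synthesize_swallow_clip(seed = s)
    expect_equal(length(clip$samples), 3 * 44100)
    segs <- detect_segments(clip)
    expect_equal(nrow(segs), 1, info = sprintf("seed %d", s))
  }
  one <- synthesize_swallow_clip(seed = 5, n_bursts = 1,
                                 burst_dur_range_s = c(0.4, 0.4))
  seg <- detect_segments(one)
  expect_lt(abs(seg$duration_s - 0.4), 0.011)
  expect_error(synthesize_swallow_clip(gap_range_s = c(0.05, 0.15)),
               class = "salivaflow_bad_gap")
  silent <- synthesize_swallow_clip(seed = 1, amplitude = 0)
  expect_true(all(silent$samples == 0))
  expect_equal(nrow(detect_segments(silent)), 0)
})

test_that("distractors carry their kind-specific signatures", {
  voc <- synthesize_distractor("vocalization", seed = 3)
  sp <- stft_spectrogram(voc)
  frame <- sp$magnitude[, 80]
  f0 <- sp$freq_hz[which.max(frame)]
  expect_gt(f0, 100)
  expect_lt(f0, 2100)                     # energy at a low harmonic
  # harmonic structure: autocorrelation of the spectrum has a strong peak
  cough <- synthesize_distractor("cough", seed = 3)
  expect_equal(nrow(detect_segments(cough)), 1)
  touch <- synthesize_distractor("touch_microphone", seed = 3)
  env <- amplitude_envelope(touch)
  expect_lte(sum(env$envelope >= 0.1 * max(env$envelope)), 3)  # one impulse
  neck <- synthesize_distractor("neck_movement", seed = 3)
  spn <- stft_spectrogram(neck)
  low <- sum(spn$magnitude[spn$freq_hz < 400, ]^2)
  expect_gt(low / sum(spn$magnitude^2), 0.9)   # low-frequency rubbing
  expect_error(synthesize_distractor("whistle"),
               class = "salivaflow_unknown_kind")
})

test_that("the labeled corpus is reproducible and standardized", {
  a <- generate_labeled_dataset(n_swallow = 5, n_distractor = 5, seed = 9)
  b <- generate_labeled_dataset(n_swallow = 5, n_distractor = 5, seed = 9)
  expect_identical(a$seed, b$seed)
  expect_identical(a$clip[[3]]$samples, b$clip[[3]]$samples)
  expect_equal(sum(a$binary_label), 5)
  expect_equal(sum(!a$binary_label), 5)
  expect_true(all(vapply(a$clip, function(cl) length(cl$samples), 0) ==
                    3 * 44100))
  expect_setequal(unique(a$label[!a$binary_label]),
                  c("vocalization", "cough", "neck_movement",
                    "touch_microphone"))
})

test_that("session audio round-trips through segmentation", {
  p <- dawes_params(flow_rate_ml_per_min = 1.2)  # event every 25 s
  s <- generate_session(p, duration_s = 120, audio = TRUE, seed = 5)
  expect_equal(nrow(s$events), 4)
  segs <- detect_segments(s$audio)
  # every planted event recovered, no false positives from the noise bed
  expect_equal(nrow(segs), nrow(s$events))
  matched <- vapply(s$events$time_s, function(t) {
    min(abs(segs$start_s - t))
  }, 0)
  expect_true(all(matched < 0.05))
  # conservation through dedup + features (planted gaps are > 2 s)
  ev <- segments_to_events(segs, rep(TRUE, nrow(segs)), window_s = 120)
  feats <- extract_features(deduplicate_events(ev), window_s = 120)
  expect_equal(feats$n_total, nrow(s$events))
  none <- generate_session(dawes_params(flow_rate_ml_per_min = 0),
                           duration_s = 60, noise_sd_g = 0, seed = 2)
  expect_equal(nrow(none$events), 0)
  expect_equal(none$saliva_g, 0)
})

test_that("trial tables look like the simulated study", {
  tr <- generate_trials(n_subjects = 4, trials_per_subject = 3, seed = 15)
  expect_equal(nrow(tr), 12)
  expect_equal(dplyr::n_distinct(tr$subject_id), 4)
  expect_true(all(tr$saliva_g >= 0))
  expect_true(all(tr$n_total == tr$n_0_100 + tr$n_100_200 + tr$n_200_300))
  again <- generate_trials(n_subjects = 4, trials_per_subject = 3, seed = 15)
  expect_identical(tr, again)
})
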