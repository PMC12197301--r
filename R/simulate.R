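# Surrogate-data generators standing in for the private study data:
# (a) a Dawes-type oral-clearance process producing swallow event streams,
# (b) a noisy cotton-method ground-truth generator (grams per 30 s),
# (c) a synthesizer for swallow sounds (1-4 band-limited bursts with
#     inter-burst gaps < 139.5 ms) and the four distractor classes, and
# (d) session/trial assemblers tying these together.

#' Oral-clearance (Dawes) simulator parameters
#'
#' Oral saliva volume rises with the secretion flow from a residual RESID
#' to a trigger VMAX; reaching VMAX fires a swallow and resets the volume
#' to RESID, so swallow frequency is proportional to secretion rate. The
#' default flow of 0.48 mL/min is the reported unstimulated norm (0.24 g
#' per 30 s at a saliva density of 1 g/mL) and, with vmax - resid =
#' 0.5 mL, gives about one swallow per minute.
#'
#' @param flow_rate_ml_per_min Secretion flow rate, mL/min (>= 0).
#' @param vmax_ml Swallow-trigger volume, mL.
#' @param resid_ml Post-swallow residual volume, mL; must be < `vmax_ml`.
#' @param flow_noise_cv Coefficient of variation of the per-interval flow
#'   (default 0: deterministic clearance).
#' @return A list of class `dawes_params`.
#' @export
dawes_params <- function(flow_rate_ml_per_min = 0.48, vmax_ml = 1.3,
                         resid_ml = 0.8, flow_noise_cv = 0) {
  stopifnot(flow_rate_ml_per_min >= 0, flow_noise_cv >= 0)
  if (!(resid_ml >= 0 && resid_ml < vmax_ml)) {
    abort("Need 0 <= resid_ml < vmax_ml.", class = "salivaflow_bad_dawes")
  }
  structure(list(flow_rate_ml_per_min = flow_rate_ml_per_min,
                 vmax_ml = vmax_ml, resid_ml = resid_ml,
                 flow_noise_cv = flow_noise_cv),
            class = "dawes_params")
}

rnorm_trunc_pos <- function(n, mean, sd, floor = 1e-6) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= floor)
  guard <- 0
  while (length(bad) && guard < 1000) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out <= floor)
    guard <- guard + 1
  }
  pmax(out, floor)
}

#' Simulate swallow events from the oral-clearance process
#'
#' Volume rises from RESID at the flow rate; a swallow fires each time it
#' reaches VMAX. With no flow noise the event count over `duration_s`
#' seconds is exactly `floor(flow * duration / 60 / (vmax - resid))`
#' (evaluated with a small relative guard so exact-integer boundaries are
#' not lost to floating-point rounding). With `flow_noise_cv > 0` the
#' per-interval flow is drawn from a zero-truncated normal.
#'
#' @param params A [dawes_params()].
#' @param duration_s Simulated duration in seconds (default 300).
#' @param seed RNG seed (only consumed when `flow_noise_cv > 0`).
#' @param trajectory_dt_s Grid step of the returned volume trajectory.
#' @return List with `events` (tibble, `time_s`) and `trajectory`
#'   (tibble, `time_s`, `volume_ml`).
#' @export
simulate_oral_clearance <- function(params, duration_s = 300, seed = 1L,
                                    trajectory_dt_s = 1) {
  stopifnot(inherits(params, "dawes_params"), duration_s > 0)
  flow <- params$flow_rate_ml_per_min
  gap_ml <- params$vmax_ml - params$resid_ml
  if (flow == 0) {
    ev <- numeric()
  } else if (params$flow_noise_cv == 0) {
    n_events <- floor(flow * duration_s / 60 / gap_ml * (1 + 1e-9))
    ev <- seq_len(n_events) * gap_ml / flow * 60
  } else {
    set.seed(seed)
    ev <- numeric()
    t <- 0
    repeat {
      f_k <- rnorm_trunc_pos(1, flow, params$flow_noise_cv * flow)
      t <- t + gap_ml / f_k * 60
      if (t > duration_s) break
      ev <- c(ev, t)
    }
  }
  grid <- seq(0, duration_s, by = trajectory_dt_s)
  t0 <- c(0, ev)
  t1 <- c(ev, Inf)
  seg <- findInterval(grid, c(0, ev), rightmost.closed = FALSE)
  vol <- numeric(length(grid))
  for (i in seq_along(grid)) {
    a <- t0[seg[i]]
    b <- t1[seg[i]]
    vol[i] <- if (is.finite(b)) {
      params$resid_ml + gap_ml * (grid[i] - a) / (b - a)
    } else {
      min(params$vmax_ml, params$resid_ml + flow * (grid[i] - a) / 60)
    }
  }
  list(events = tibble(time_s = ev),
       trajectory = tibble(time_s = grid, volume_ml = vol))
}

#' Simulate a cotton-method ground-truth measurement
#'
#' Grams of saliva collected in 30 s at the given flow: `flow * 0.5 min *
#' 1 g/mL` plus Gaussian measurement noise, clipped at zero (a cotton roll
#' cannot lose weight).
#'
#' @param flow_rate_ml_per_min Secretion flow rate(s), mL/min.
#' @param noise_sd_g Measurement noise SD in grams (default 0.03).
#' @param seed Optional RNG seed.
#' @return Numeric vector of grams per 30 s, same length as the flow.
#' @export
simulate_cotton_measurement <- function(flow_rate_ml_per_min,
                                        noise_sd_g = 0.03, seed = NULL) {
  stopifnot(all(flow_rate_ml_per_min >= 0), noise_sd_g >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(flow_rate_ml_per_min)
  pmax(0, flow_rate_ml_per_min * 0.5 + rnorm(n, 0, noise_sd_g))
}

trapezoid_env <- function(n, sr, ramp_s = 0.010) {
  r <- max(2L, min(as.integer(round(ramp_s * sr)), n %/% 2))
  up <- sin(seq(0, pi / 2, length.out = r))^2
  c(up, rep(1, n - 2 * r), rev(up))
}

bandpass_noise <- function(n, sr, band_hz) {
  bf <- signal::butter(4, band_hz / (sr / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bf, rnorm(n + 2000)))
  x <- x[1001:(1000 + n)]
  x / max(abs(x))
}

#' Synthesize a swallow sound clip
#'
#' One to four band-limited noise bursts with trapezoid-enveloped onsets,
#' separated by gaps strictly shorter than 139.5 ms, inside a fixed-length
#' clip, so the segmenter returns exactly one segment per swallow. These
#' are declared plausible stand-ins for real swallow acoustics (the band
#' matches the throat microphone's 200 Hz - 3 kHz range), not
#' reconstructions.
#'
#' @param sample_rate_hz Sample rate (default 44100).
#' @param seed RNG seed.
#' @param n_bursts Number of bursts (1-4); drawn uniformly when NULL.
#' @param burst_dur_range_s Burst duration range, seconds.
#' @param gap_range_s Inter-burst gap range, seconds; every gap must be
#'   < 0.1395 or the call is rejected.
#' @param band_hz Spectral band of the burst noise.
#' @param amplitude Peak amplitude in (0, 1].
#' @param clip_s Clip length (default 3).
#' @param start_s Onset time of the first burst.
#' @return A standardized [audio_clip()] of `clip_s` seconds.
#' @export
synthesize_swallow_clip <- function(sample_rate_hz = 44100, seed = 1L,
                                    n_bursts = NULL,
                                    burst_dur_range_s = c(0.08, 0.30),
                                    gap_range_s = c(0.03, 0.12),
                                    band_hz = c(200, 3000),
                                    amplitude = 0.8, clip_s = 3,
                                    start_s = 0.2) {
  if (max(gap_range_s) >= 0.1395) {
    abort("Inter-burst gaps must be strictly < 0.1395 s for a single swallow.",
          class = "salivaflow_bad_gap")
  }
  stopifnot(amplitude >= 0, clip_s > 0, start_s >= 0)
  set.seed(seed)
  nb <- n_bursts %||% sample(1:4, 1)
  stopifnot(nb >= 1, nb <= 4)
  sr <- sample_rate_hz
  x <- numeric(as.integer(round(clip_s * sr)))
  t <- start_s
  for (b in seq_len(nb)) {
    dur <- runif(1, burst_dur_range_s[1], burst_dur_range_s[2])
    n <- as.integer(round(dur * sr))
    burst <- bandpass_noise(n, sr, band_hz) * trapezoid_env(n, sr) *
      amplitude * runif(1, 0.7, 1)
    i0 <- as.integer(round(t * sr)) + 1L
    i1 <- min(length(x), i0 + n - 1L)
    if (i0 <= length(x)) x[i0:i1] <- x[i0:i1] + burst[seq_len(i1 - i0 + 1L)]
    t <- t + dur + runif(1, gap_range_s[1], gap_range_s[2])
  }
  if (amplitude > 0 && max(abs(x)) > 0) x <- x * amplitude / max(abs(x))
  audio_clip(x, sr)
}

#' Synthesize a non-swallow distractor clip
#'
#' Kind-specific signatures, distinguishable from swallow bursts by
#' construction: `vocalization` a harmonic tone stack on a random
#' fundamental; `cough` a single long broadband burst with a sharp attack
#' and exponential decay; `neck_movement` slow low-frequency rubbing
#' noise; `touch_microphone` one sharp impulse.
#'
#' @param kind One of `"vocalization"`, `"cough"`, `"neck_movement"`,
#'   `"touch_microphone"`.
#' @param sample_rate_hz Sample rate (default 44100).
#' @param seed RNG seed.
#' @param amplitude Peak amplitude.
#' @param clip_s Clip length (default 3).
#' @return A standardized [audio_clip()].
#' @export
synthesize_distractor <- function(kind, sample_rate_hz = 44100, seed = 1L,
                                  amplitude = 0.8, clip_s = 3) {
  kinds <- c("vocalization", "cough", "neck_movement", "touch_microphone")
  if (!kind %in% kinds) {
    abort(sprintf("Unknown distractor kind '%s'.", kind),
          class = "salivaflow_unknown_kind")
  }
  set.seed(seed)
  sr <- sample_rate_hz
  x <- numeric(as.integer(round(clip_s * sr)))
  start <- 0.2
  if (kind == "vocalization") {
    f0 <- runif(1, 120, 250)
    dur <- runif(1, 0.8, 1.5)
    n <- as.integer(round(dur * sr))
    tt <- seq_len(n) / sr
    tone <- Reduce(`+`, purrr::map(1:8, ~ sin(2 * pi * f0 * .x * tt +
                                                runif(1, 0, 2 * pi)) / .x))
    seg <- tone / max(abs(tone)) * trapezoid_env(n, sr, 0.05)
  } else if (kind == "cough") {
    dur <- runif(1, 0.25, 0.5)
    n <- as.integer(round(dur * sr))
    decay <- exp(-seq_len(n) / (0.12 * sr))
    seg <- bandpass_noise(n, sr, c(300, 4000)) * decay *
      trapezoid_env(n, sr, 0.004)
  } else if (kind == "neck_movement") {
    dur <- runif(1, 1.0, 2.0)
    n <- as.integer(round(dur * sr))
    am <- 0.6 + 0.4 * sin(2 * pi * runif(1, 1, 3) * seq_len(n) / sr)
    seg <- bandpass_noise(n, sr, c(60, 300)) * am * trapezoid_env(n, sr, 0.05)
  } else { # touch_microphone
    dur <- 0.02
    n <- as.integer(round(dur * sr))
    seg <- bandpass_noise(n, sr, c(500, 6000)) * exp(-seq_len(n) / (0.003 * sr))
  }
  i0 <- as.integer(round(start * sr)) + 1L
  i1 <- min(length(x), i0 + length(seg) - 1L)
  x[i0:i1] <- seg[seq_len(i1 - i0 + 1L)]
  if (max(abs(x)) > 0) x <- x * amplitude / max(abs(x))
  audio_clip(x, sr)
}

#' Generate a labeled clip corpus
#'
#' Reproducible synthetic stand-in for the study's recorded corpus of
#' 3-second swallow and non-swallow clips. Distractors cycle through the
#' four kinds; pseudo-subject ids are assigned in blocks within each
#' class so every subject contributes both classes.
#'
#' @param n_swallow,n_distractor Class sizes.
#' @param sample_rate_hz Sample rate of the clips.
#' @param seed Master seed; per-clip seeds are derived from it, so the
#'   corpus is byte-identical across reruns.
#' @param n_subjects Number of pseudo-subjects.
#' @return Tibble with `clip_id`, `clip` (list of [audio_clip()]), `label`
#'   (5-class), `binary_label` (swallow vs other), `subject_id`, `seed`.
#' @export
generate_labeled_dataset <- function(n_swallow = 100, n_distractor = 100,
                                     sample_rate_hz = 44100, seed = 1L,
                                     n_subjects = 10) {
  stopifnot(n_swallow >= 1, n_distractor >= 1)
  set.seed(seed)
  n <- n_swallow + n_distractor
  clip_seeds <- sample.int(2^30, n)
  kinds <- rep_len(c("vocalization", "cough", "neck_movement",
                     "touch_microphone"), n_distractor)
  label <- c(rep("swallow", n_swallow), kinds)
  subject_id <- c(rep_len(sprintf("S%02d", seq_len(n_subjects)), n_swallow),
                  rep_len(sprintf("S%02d", seq_len(n_subjects)), n_distractor))
  clips <- map(seq_len(n), function(i) {
    if (label[i] == "swallow") {
      synthesize_swallow_clip(sample_rate_hz, seed = clip_seeds[i])
    } else {
      synthesize_distractor(label[i], sample_rate_hz, seed = clip_seeds[i])
    }
  })
  tibble(clip_id = seq_len(n), clip = clips, label = label,
         binary_label = label == "swallow", subject_id = subject_id,
         seed = clip_seeds)
}

# FFT-shaped 1/f (pink) noise, unit peak.
pink_noise <- function(n) {
  white <- rnorm(n)
  sp <- fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  shaped <- Re(fft(sp / sqrt(f), inverse = TRUE)) / n
  shaped / max(abs(shaped))
}

#' Generate a full observation session
#'
#' Runs the oral-clearance simulator over an observation window, draws the
#' matching noisy cotton-method ground truth, and (optionally) renders the
#' session as audio: swallow clips placed at the event times over a
#' low-level pink-noise bed at 1% of the burst amplitude, so the 10%
#' relative threshold rule is exercised realistically.
#'
#' @param params A [dawes_params()].
#' @param duration_s Window length (default 300 s).
#' @param audio Also render session audio (default FALSE).
#' @param noise_sd_g Ground-truth measurement noise SD in grams.
#' @param sample_rate_hz Audio sample rate.
#' @param seed RNG seed.
#' @return List with `events` (tibble), `saliva_g` (ground truth, grams
#'   per 30 s), `params`, and `audio` (an [audio_clip()] or NULL).
#' @export
generate_session <- function(params = dawes_params(), duration_s = 300,
                             audio = FALSE, noise_sd_g = 0.03,
                             sample_rate_hz = 44100, seed = 1L) {
  sim <- simulate_oral_clearance(params, duration_s, seed = seed)
  saliva_g <- simulate_cotton_measurement(params$flow_rate_ml_per_min,
                                          noise_sd_g, seed = seed + 1L)
  clip <- NULL
  if (audio) {
    set.seed(seed + 2L)
    sr <- sample_rate_hz
    n <- as.integer(round(duration_s * sr))
    burst_amp <- 0.8
    x <- pink_noise(n) * 0.01 * burst_amp
    ev_seeds <- sample.int(2^30, max(1, nrow(sim$events)))
    for (i in seq_len(nrow(sim$events))) {
      sw <- synthesize_swallow_clip(sr, seed = ev_seeds[i], start_s = 0,
                                    amplitude = burst_amp)
      i0 <- as.integer(round(sim$events$time_s[i] * sr)) + 1L
      i1 <- min(n, i0 + length(sw$samples) - 1L)
      if (i0 <= n) {
        x[i0:i1] <- x[i0:i1] + sw$samples[seq_len(i1 - i0 + 1L)]
      }
    }
    clip <- audio_clip(pmax(-1, pmin(1, x)), sr)
  }
  list(events = sim$events, saliva_g = saliva_g, params = params,
       audio = clip)
}

#' Generate a table of simulated measurement trials
#'
#' The synthetic analogue of a multi-subject estimation study: each
#' pseudo-subject has a latent mean secretion flow (normal across
#' subjects), each trial perturbs it (normal within subject), swallow
#' events over 5 minutes come from the oral-clearance process, the five
#' timing features are extracted after consecutive-swallow suppression,
#' and the ground truth is a noisy cotton-method draw. Default population
#' constants (mean flow 0.48 mL/min, between-subject SD 0.103, within-
#' subject SD 0.100 mL/min, measurement noise 0.03 g) reproduce the
#' reported variability regime of unstimulated secretion.
#'
#' @param n_subjects Number of pseudo-subjects (default 17).
#' @param trials_per_subject Trials per subject (default 5).
#' @param mean_flow_ml_per_min Population mean flow.
#' @param between_sd_ml_per_min Between-subject SD of the mean flow.
#' @param within_sd_ml_per_min Within-subject trial-to-trial SD.
#' @param noise_sd_g Cotton-method measurement noise SD, grams.
#' @param window_s Observation window per trial (default 300 s).
#' @param vmax_ml,resid_ml Clearance volumes (defaults as in
#'   [dawes_params()]).
#' @param seed Master seed.
#' @return Tibble with `subject_id`, `trial`, `flow_rate_ml_per_min`, the
#'   five feature columns, and `saliva_g`.
#' @export
generate_trials <- function(n_subjects = 17, trials_per_subject = 5,
                            mean_flow_ml_per_min = 0.48,
                            between_sd_ml_per_min = 0.103,
                            within_sd_ml_per_min = 0.100,
                            noise_sd_g = 0.03, window_s = 300,
                            vmax_ml = 1.3, resid_ml = 0.8, seed = 1L) {
  set.seed(seed)
  subj_flow <- rnorm_trunc_pos(n_subjects, mean_flow_ml_per_min,
                               between_sd_ml_per_min, floor = 0.02)
  rows <- purrr::map_dfr(seq_len(n_subjects), function(s) {
    flows <- rnorm_trunc_pos(trials_per_subject, subj_flow[s],
                             within_sd_ml_per_min, floor = 0.02)
    noise <- rnorm(trials_per_subject, 0, noise_sd_g)
    purrr::map_dfr(seq_len(trials_per_subject), function(k) {
      p <- dawes_params(flow_rate_ml_per_min = flows[k],
                        vmax_ml = vmax_ml, resid_ml = resid_ml)
      ev <- simulate_oral_clearance(p, window_s)$events
      feats <- extract_features(deduplicate_events(ev), window_s)
      dplyr::bind_cols(
        tibble(subject_id = sprintf("S%02d", s), trial = k,
               flow_rate_ml_per_min = flows[k]),
        feats,
        tibble(saliva_g = pmax(0, flows[k] * 0.5 + noise[k])))
    })
  })
  rows
}
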