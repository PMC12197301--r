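# Time-frequency front-ends for the swallow classifier: a short-time
# Fourier spectrogram (10.1 ms window, 5.05 ms hop) and a continuous
# wavelet scalogram with the complex Gaussian order-5 mother wavelet
# (cgau5), rendered as 224x224x3 images.

#' Short-time Fourier spectrogram
#'
#' Hann-windowed STFT magnitude. Window and hop are given in seconds and
#' converted to sample counts at the clip's own rate (at 44100 Hz the
#' defaults round to 445 and 223 samples).
#'
#' @param clip An [audio_clip()] at least one window long.
#' @param window_s Analysis window length in seconds (default 0.0101).
#' @param hop_s Hop between adjacent frames in seconds (default 0.00505,
#'   i.e. 50% overlap).
#' @return A list of class `stft_spec`: `magnitude` (freq bins x frames,
#'   non-negative), `freq_hz`, `time_s` (frame start times), `window_samples`,
#'   `hop_samples`. Frame count is `1 + floor((n - window) / hop)`.
#' @export
stft_spectrogram <- function(clip, window_s = 0.0101, hop_s = 0.00505) {
  stopifnot(inherits(clip, "audio_clip"), window_s > 0, hop_s > 0,
            hop_s <= window_s)
  sr <- clip$sample_rate_hz
  win <- max(2L, as.integer(round(window_s * sr)))
  hop <- max(1L, as.integer(round(hop_s * sr)))
  n <- length(clip$samples)
  if (n < win) {
    abort("Clip is shorter than one STFT window.",
          class = "salivaflow_clip_too_short")
  }
  sg <- signal::specgram(clip$samples, n = win, Fs = sr,
                         window = signal::hanning(win), overlap = win - hop)
  structure(list(magnitude = abs(sg$S),
                 freq_hz = as.numeric(sg$f),
                 time_s = as.numeric(sg$t) - win / (2 * sr),
                 window_samples = win, hop_samples = hop),
            class = "stft_spec")
}

# Polynomial coefficients (complex, ascending powers of t) of the 5th
# derivative of exp(-i t - t^2), via the recurrence p_{k+1} = p_k' + (-i-2t) p_k.
cgau_poly <- function(order) {
  p <- c(1 + 0i)
  for (k in seq_len(order)) {
    dp <- if (length(p) > 1) p[-1] * seq_len(length(p) - 1) else 0 + 0i
    tp <- c(0 + 0i, -2 * p)            # -2t * p
    ip <- -1i * p                      # -i * p
    m <- max(length(dp), length(tp), length(ip))
    pad <- function(v) c(v, numeric(m - length(v)))
    p <- pad(dp) + pad(tp) + pad(ip)
  }
  p
}

# Sample the unit-energy cgau wavelet psi(t) on a time grid. The L2
# normalization constant is computed once per order and cached.
cgau_psi <- function(t, order = 5) {
  key <- as.character(order)
  p <- cgau_poly(order)
  poly <- Reduce(`+`, purrr::map(seq_along(p), ~ p[.x] * t^(.x - 1)))
  raw <- poly * exp(-1i * t - t^2)
  if (is.null(.cgau_cache$norm[[key]])) {
    tt <- seq(-8, 8, length.out = 2^12)
    pref <- Reduce(`+`, purrr::map(seq_along(p), ~ p[.x] * tt^(.x - 1)))
    .cgau_cache$norm[[key]] <-
      sqrt(sum(Mod(pref * exp(-1i * tt - tt^2))^2) * (tt[2] - tt[1]))
  }
  raw / .cgau_cache$norm[[key]]
}

#' Center frequency of the cgau5 wavelet
#'
#' The dominant frequency (in cycles per unit of the wavelet's own time
#' axis) of the complex Gaussian wavelet, found from the peak of its
#' spectrum; used to convert scales to pseudo-frequencies via
#' `f = fc / (scale * dt)`.
#'
#' @param order Derivative order of the complex Gaussian (default 5).
#' @return Center frequency, cycles per unit time.
#' @export
cgau_center_frequency <- function(order = 5) {
  key <- as.character(order)
  if (!is.null(.cgau_cache$fc[[key]])) return(.cgau_cache$fc[[key]])
  n <- 2^13
  pad <- 2^17                 # zero-padding refines the frequency grid
  t <- seq(-8, 8, length.out = n)
  psi <- cgau_psi(t, order)
  sp <- Mod(fft(c(psi, complex(pad - n))))
  dt <- t[2] - t[1]
  freqs <- c(seq(0, pad / 2 - 1), seq(-pad / 2, -1)) / (pad * dt)
  fc <- abs(freqs[which.max(sp)])
  .cgau_cache$fc[[key]] <- fc
  fc
}

.cgau_cache <- new.env(parent = emptyenv())
.cgau_cache$fc <- list()
.cgau_cache$norm <- list()

#' Default CWT scales for a sample rate
#'
#' 19 logarithmically spaced scales whose pseudo-frequencies span the
#' throat microphone's 200 Hz - 3 kHz band, returned in increasing order.
#'
#' @param sample_rate_hz Sample rate of the clips to analyse.
#' @param n_scales Number of scales (default 19).
#' @param freq_range_hz Pseudo-frequency band covered (default c(200, 3000)).
#' @return Strictly increasing numeric vector of scales.
#' @export
default_cwt_scales <- function(sample_rate_hz, n_scales = 19,
                               freq_range_hz = c(200, 3000)) {
  fc <- cgau_center_frequency()
  freqs <- exp(seq(log(max(freq_range_hz)), log(min(freq_range_hz)),
                   length.out = n_scales))
  fc * sample_rate_hz / freqs
}

#' Continuous wavelet scalogram (complex Gaussian, gaus5)
#'
#' Modulus of the CWT of the clip with the order-5 complex Gaussian mother
#' wavelet, computed by FFT convolution with the analytically sampled
#' wavelet at each scale.
#'
#' @param clip A non-empty [audio_clip()].
#' @param scales Strictly increasing positive scales; default
#'   [default_cwt_scales()] at the clip's rate.
#' @param order Complex Gaussian derivative order (default 5).
#' @return A list of class `cwt_scalogram`: `magnitude`
#'   (`length(scales)` x `length(samples)`, non-negative), `scales`,
#'   `pseudo_freq_hz`, `sample_rate_hz`.
#' @export
cwt_scalogram <- function(clip, scales = NULL, order = 5) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!length(clip$samples)) {
    abort("Cannot transform an empty clip.", class = "salivaflow_empty_clip")
  }
  if (is.null(scales)) scales <- default_cwt_scales(clip$sample_rate_hz)
  if (!length(scales)) {
    abort("`scales` must be non-empty.", class = "salivaflow_bad_scales")
  }
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE)) {
    abort("`scales` must be strictly increasing and positive.",
          class = "salivaflow_bad_scales")
  }
  x <- clip$samples
  n <- length(x)
  max_m <- ceiling(5 * max(scales))
  len <- stats::nextn(n + 2 * max_m + 1, 2)
  fx <- fft(c(x, numeric(len - n)))
  fc <- cgau_center_frequency(order)
  mag <- matrix(0, nrow = length(scales), ncol = n)
  for (k in seq_along(scales)) {
    s <- scales[k]
    m <- ceiling(5 * s)
    u <- (-m:m) / s                      # wavelet time axis (dt = 1 sample)
    # L1 scale normalization: equal-amplitude sinusoids give equal modulus
    # across scales, so the peak row sits at the nearest pseudo-frequency.
    h <- Conj(cgau_psi(u, order)) / s
    g <- rev(h)                          # correlation via convolution
    fg <- fft(c(g, numeric(len - length(g))))
    y <- fft(fx * fg, inverse = TRUE) / len
    mag[k, ] <- Mod(y[(m + 1):(m + n)])
  }
  structure(list(magnitude = mag, scales = scales,
                 pseudo_freq_hz = fc * clip$sample_rate_hz / scales,
                 sample_rate_hz = clip$sample_rate_hz),
            class = "cwt_scalogram")
}

#' Convert a non-negative matrix to a normalized 224x224x3 image
#'
#' Optionally log-compresses (`log(1 + x)`, appropriate for the wide
#' dynamic range of swallow bursts), bilinearly resizes to the target
#' size, min-max normalizes to \[0, 1\], and replicates across 3 channels
#' (or maps through a simple blue-red colormap). A constant input maps to
#' an all-zero image.
#'
#' @param mat Non-empty numeric matrix with non-negative entries, or an
#'   `stft_spec` / `cwt_scalogram` object (its magnitude is used).
#' @param size Output height/width (default 224).
#' @param log_compress Apply `log1p` before resizing (default TRUE).
#' @param colormap `"gray"` (channel replication, default) or `"bluered"`.
#' @return Numeric array `size x size x 3` with values in \[0, 1\].
#' @export
to_image <- function(mat, size = 224, log_compress = TRUE,
                     colormap = c("gray", "bluered")) {
  colormap <- match.arg(colormap)
  if (inherits(mat, "stft_spec") || inherits(mat, "cwt_scalogram")) {
    mat <- mat$magnitude
  }
  stopifnot(is.matrix(mat), length(mat) > 0)
  if (log_compress) mat <- log1p(mat)
  resized <- if (all(dim(mat) == c(size, size))) {
    mat
  } else {
    EBImage::imageData(EBImage::resize(EBImage::as.Image(mat),
                                       w = size, h = size))
  }
  rng <- range(resized)
  norm <- if (rng[2] > rng[1]) (resized - rng[1]) / (rng[2] - rng[1]) else
    matrix(0, size, size)
  out <- array(0, c(size, size, 3))
  if (colormap == "gray") {
    out[, , 1] <- norm; out[, , 2] <- norm; out[, , 3] <- norm
  } else {
    out[, , 1] <- norm                 # red ramps up
    out[, , 2] <- 1 - abs(2 * norm - 1) # green peaks mid-scale
    out[, , 3] <- 1 - norm             # blue ramps down
  }
  out
}
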