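test_that("write/read round trip preserves samples within PCM quantization", {
  set.seed(1)
  clip <- audio_clip(runif(4410, -1, 1))
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, f)
  back <- read_wav(f)
  expect_equal(length(back$samples), length(clip$samples))
  expect_equal(back$sample_rate_hz, 44100)
  expect_lt(max(abs(back$samples - clip$samples)), 1 / 32768 + 1e-12)
})

test_that("a full-scale sine hits the 16-bit rails", {
  t <- seq(0, 0.1, by = 1 / 44100)
  clip <- audio_clip(sin(2 * pi * 440 * t))
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, f)
  pcm_peak <- max(read_wav(f)$samples) * 32768
  expect_lte(abs(pcm_peak - 32767), 1)
})

test_that("silence round-trips to exact zeros", {
  clip <- audio_clip(numeric(44100))
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, f)
  expect_true(all(read_wav(f)$samples == 0))
})

test_that("stereo input is averaged to mono", {
  # hand-built stereo RIFF with channels (x, -x): averaging cancels to zero
  x <- as.integer(round(runif(1000, -1, 1) * 32767))
  f <- withr::local_tempfile(fileext = ".wav")
  con <- file(f, "wb")
  interleaved <- as.integer(rbind(x, -x))
  data_size <- 2L * length(interleaved)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(2L, con, 2, endian = "little")   # stereo
  writeBin(44100L, con, 4, endian = "little")
  writeBin(44100L * 4L, con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(interleaved, con, 2, endian = "little")
  close(con)
  back <- read_wav(f)
  expect_equal(length(back$samples), 1000)
  expect_true(all(back$samples == 0))
})

test_that("reader raises distinct, named errors", {
  expect_error(read_wav(file.path(tempdir(), "no-such-file.wav")),
               class = "salivaflow_wav_missing")
  f <- withr::local_tempfile(fileext = ".wav")
  writeLines("this is not audio at all, just text padding", f)
  expect_error(read_wav(f), class = "salivaflow_wav_format")
  # structurally valid WAV with an empty data chunk
  f2 <- withr::local_tempfile(fileext = ".wav")
  con <- file(f2, "wb")
  writeChar("RIFF", con, eos = NULL); writeBin(36L, con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little"); writeBin(1L, con, 2, endian = "little")
  writeBin(44100L, con, 4, endian = "little")
  writeBin(88200L, con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little"); writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL); writeBin(0L, con, 4, endian = "little")
  close(con)
  expect_error(read_wav(f2), class = "salivaflow_wav_empty")
})

test_that("peak_normalize is idempotent, scale-invariant, and keeps zeros", {
  set.seed(2)
  clip <- audio_clip(rnorm(1000) * 0.1)
  normed <- peak_normalize(clip)
  expect_equal(max(abs(normed$samples)), 1.0)
  expect_equal(peak_normalize(normed)$samples, normed$samples)
  scaled <- clip
  scaled$samples <- clip$samples * 0.3
  expect_equal(peak_normalize(scaled)$samples, normed$samples)
  zero <- audio_clip(numeric(10))
  expect_equal(peak_normalize(zero)$samples, numeric(10))
  expect_error(peak_normalize(audio_clip(numeric(0))),
               class = "salivaflow_empty_clip")
})

test_that("clip construction validates its invariants", {
  expect_error(audio_clip(c(0, NA, 1)), class = "salivaflow_bad_samples")
  expect_error(audio_clip(0, sample_rate_hz = -1),
               class = "salivaflow_bad_rate")
  expect_warning(audio_clip(numeric(10), 8000),
                 class = "salivaflow_rate_warning")
})
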