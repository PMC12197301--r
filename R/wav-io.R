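# RIFF/WAVE PCM reader and writer. Only uncompressed integer PCM is handled
# (16-bit on write; 8/16/24/32-bit on read); that covers every file the
# pipeline produces or is expected to ingest.

#' Read a PCM WAV file as a mono audio clip
#'
#' Multi-channel files are averaged to mono; the sample rate is preserved.
#' Integer PCM is mapped to floating amplitude in \[-1, 1\].
#'
#' @param path Path to a RIFF/WAVE PCM file.
#' @return An [audio_clip()].
#' @section Errors:
#' * `salivaflow_wav_missing` — the file does not exist.
#' * `salivaflow_wav_format` — the payload is not RIFF/WAVE integer PCM.
#' * `salivaflow_wav_empty` — the data chunk holds zero samples.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("WAV file not found: %s", path),
          class = "salivaflow_wav_missing")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) {
    abort("Not a RIFF file.", class = "salivaflow_wav_format")
  }
  invisible(readBin(con, "integer", 1, 4, endian = "little")) # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    abort("RIFF payload is not WAVE.", class = "salivaflow_wav_format")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size + size %% 2)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        n_channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE,
                             endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, signed = FALSE,
                       endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort("WAV file lacks fmt or data chunk.", class = "salivaflow_wav_format")
  }
  if (fmt$audio_format != 1L) {
    abort(sprintf("Unsupported WAV audio format %d (only integer PCM).",
                  fmt$audio_format), class = "salivaflow_wav_format")
  }
  if (!fmt$bits %in% c(8L, 16L, 24L, 32L)) {
    abort(sprintf("Unsupported bit depth %d.", fmt$bits),
          class = "salivaflow_wav_format")
  }
  if (length(data_raw) == 0) {
    abort("WAV data chunk is empty.", class = "salivaflow_wav_empty")
  }
  x <- decode_pcm(data_raw, fmt$bits)
  if (fmt$n_channels > 1) {
    n <- length(x) %/% fmt$n_channels
    x <- rowMeans(matrix(x[seq_len(n * fmt$n_channels)],
                         nrow = n, byrow = TRUE))
  }
  if (length(x) == 0) {
    abort("WAV data chunk is empty.", class = "salivaflow_wav_empty")
  }
  suppressWarnings(audio_clip(x, fmt$sample_rate))
}

decode_pcm <- function(raw, bits) {
  switch(as.character(bits),
    "8" = (as.integer(raw) - 128) / 128,
    "16" = readBin(raw, "integer", length(raw) %/% 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(raw) %/% 3
      b <- matrix(as.integer(raw[seq_len(n * 3)]), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 2^23, v - 2^24, v)
      v / 2^23
    },
    "32" = readBin(raw, "integer", length(raw) %/% 4, 4,
                   signed = TRUE, endian = "little") / 2^31
  )
}

#' Write a mono audio clip as 16-bit PCM WAV
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16-bit signed integers,
#' so `read_wav(write_wav(clip, f))` reproduces `clip` within one
#' quantization step (1/32768) per sample.
#'
#' @param clip An [audio_clip()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort(
                    sprintf("Cannot open '%s' for writing.", path),
                    class = "salivaflow_wav_unwritable"))
  on.exit(close(con))
  x <- pmax(-1, pmin(1, clip$samples))
  pcm <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  n <- length(pcm)
  sr <- clip$sample_rate_hz
  data_size <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")        # PCM
  writeBin(1L, con, 2, endian = "little")        # mono
  writeBin(as.integer(sr), con, 4, endian = "little")
  writeBin(as.integer(sr * 2L), con, 4, endian = "little")  # byte rate
  writeBin(2L, con, 2, endian = "little")        # block align
  writeBin(16L, con, 2, endian = "little")       # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
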