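## Minimal RIFF/WAVE PCM I/O.  The pipeline's exchange format is 16-bit
## mono PCM at 16 kHz; the reader additionally accepts 8/32-bit integer PCM
## and stereo (averaged to mono), and resamples non-16 kHz material.

#' Read a WAV file
#'
#' Reads an integer-PCM RIFF/WAVE file to a mono [audio_clip()] with samples
#' in `[-1, 1]`.  Stereo (or higher channel counts) are averaged to mono.
#' Files whose sampling rate is not `target_rate` are resampled (polyphase,
#' [signal::resample()]) so downstream stages always see 16 kHz material.
#'
#' @param path Path to a WAV file.
#' @param target_rate Rate the clip is brought to; default 16000 Hz.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path, target_rate = 16000L) {
  if (!file.exists(path)) stop("read_wav: file does not exist: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) stop("read_wav: not a WAV file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("read_wav: not a RIFF/WAVE file: ", path)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(len) == 0) break
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", len)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", len)
    } else {
      invisible(readBin(con, "raw", len))
    }
    if (len %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("read_wav: malformed WAV (missing fmt/data chunk): ", path)
  }
  if (fmt$audio_format != 1) {
    stop("read_wav: only integer PCM supported (format tag ", fmt$audio_format, ")")
  }
  bytes <- fmt$bits / 8
  n <- length(data_raw) %/% (bytes * fmt$n_channels)
  if (n == 0) stop("read_wav: empty data chunk: ", path)
  x <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", n * fmt$n_channels, 1,
                               signed = FALSE)) - 128) / 128,
    "16" = pmax(as.numeric(readBin(data_raw, "integer", n * fmt$n_channels,
                                   2, signed = TRUE,
                                   endian = "little")) / 32767, -1),
    "32" = as.numeric(readBin(data_raw, "integer", n * fmt$n_channels, 4,
                              endian = "little")) / 2147483648,
    stop("read_wav: unsupported bit depth: ", fmt$bits))
  if (fmt$n_channels > 1) {
    x <- rowMeans(matrix(x, ncol = fmt$n_channels, byrow = TRUE))
  }
  if (fmt$sample_rate != target_rate) {
    g <- gcd_int(target_rate, fmt$sample_rate)
    x <- signal::resample(x, target_rate / g, fmt$sample_rate / g)
    x[x > 1] <- 1; x[x < -1] <- -1
  }
  audio_clip(x, target_rate, source_path = path)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Write a 16-bit PCM WAV file
#'
#' @param clip An [audio_clip()] (samples clipped to `[-1, 1]` on write).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot_clip(clip)
  x <- clip$samples
  x[x > 1] <- 1; x[x < -1] <- -1
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_len, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(clip$sample_rate, con, size = 4, endian = "little")
  writeBin(clip$sample_rate * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")                 # block align
  writeBin(16L, con, size = 2, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
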