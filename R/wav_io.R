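# RIFF/WAVE reading and writing on base readBin/writeBin. Supports the PCM
# integer (format 1) and IEEE float (format 3) dialects, mono or multi-channel
# in; output is always mono PCM16.

#' Read a WAV file as an audio signal
#'
#' Multi-channel recordings are averaged to mono (stethoscope audio is
#' nominally single-channel). Integer PCM samples are rescaled to \[-1, 1\].
#' A file whose data payload is empty raises a catchable condition of class
#' `pcgnet_empty_signal_error`, so a batch run can skip silent/contentless
#' files instead of aborting.
#'
#' @param path Path to a RIFF/WAVE file (PCM 8/16/24/32-bit or IEEE
#'   float32/float64).
#' @param label Optional class label to attach.
#' @return An [audio_signal] with `fs` taken from the file header and
#'   `source_id` set to the file name.
#' @export
read_wav <- function(path, label = NULL) {
  pcg_assert(file.exists(path), "pcgnet_io_error",
             sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF"))
    pcg_error("pcgnet_format_error", sprintf("not a RIFF file: %s", path))
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    pcg_error("pcgnet_format_error", sprintf("not a WAVE file: %s", path))

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      chunk <- readBin(con, "raw", size)
      if (length(chunk) < 16)
        pcg_error("pcgnet_format_error", "truncated fmt chunk")
      u16 <- function(off) sum(as.integer(chunk[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.numeric(chunk[off + 1:4]) * c(1, 256, 65536, 16777216))
      fmt <- list(code = u16(0), channels = u16(2), fs = u32(4),
                  bits = u16(14))
      if (fmt$code == 65534 && length(chunk) >= 26) # WAVE_FORMAT_EXTENSIBLE
        fmt$code <- u16(24)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size)
        pcg_error("pcgnet_format_error", sprintf("truncated data chunk in %s", path))
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2)) # skip, chunks are word-aligned
    }
  }
  if (is.null(fmt) || is.null(data_raw))
    pcg_error("pcgnet_format_error", sprintf("missing fmt/data chunk in %s", path))
  if (length(data_raw) == 0)
    pcg_error("pcgnet_empty_signal_error",
              sprintf("WAV file has no audio content: %s", path))

  bytes <- fmt$bits %/% 8
  n_total <- length(data_raw) %/% bytes
  if (n_total == 0)
    pcg_error("pcgnet_empty_signal_error",
              sprintf("WAV file has no audio content: %s", path))
  x <- switch(
    as.character(fmt$code),
    "1" = { # integer PCM
      # scaled by the positive full-scale value (2^(bits-1) - 1), the same
      # scale write_wav uses, so write/read is identity up to half an LSB
      if (fmt$bits == 8) {
        pmax(-1, (as.numeric(readBin(data_raw, "integer", n_total, size = 1,
                                     signed = FALSE)) - 128) / 127)
      } else if (fmt$bits == 16) {
        pmax(-1, readBin(data_raw, "integer", n_total, size = 2, signed = TRUE,
                         endian = "little") / 32767)
      } else if (fmt$bits == 24) {
        m <- matrix(as.integer(data_raw[seq_len(n_total * 3)]), nrow = 3)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        pmax(-1, v / 8388607)
      } else if (fmt$bits == 32) {
        pmax(-1, readBin(data_raw, "integer", n_total, size = 4,
                         endian = "little") / 2147483647)
      } else pcg_error("pcgnet_format_error",
                       sprintf("unsupported PCM bit depth: %d", fmt$bits))
    },
    "3" = { # IEEE float
      readBin(data_raw, "double", n_total, size = bytes, endian = "little")
    },
    pcg_error("pcgnet_format_error",
              sprintf("unsupported WAV format code: %d", fmt$code))
  )
  if (fmt$channels > 1) {
    n_frames <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$channels)],
                         nrow = fmt$channels))
  }
  if (length(x) == 0)
    pcg_error("pcgnet_empty_signal_error",
              sprintf("WAV file has no audio content: %s", path))
  audio_signal(x, fs = fmt$fs, source_id = basename(path), label = label)
}

#' Write an audio signal as a mono PCM16 WAV file
#'
#' `read_wav(write_wav(s, p))` reproduces the samples up to 16-bit
#' quantization (absolute error at most 2^-15). Amplitudes outside \[-1, 1\]
#' are clipped.
#'
#' @param signal An [audio_signal] with finite samples.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  pcg_assert(all(is.finite(signal$samples)), "pcgnet_validation_error",
             "samples must all be finite")
  pcg_assert(signal$fs == round(signal$fs) && signal$fs > 0,
             "pcgnet_validation_error", "fs must be a positive integer")
  x <- pmax(-1, pmin(1, signal$samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- tryCatch(file(path, "wb"),
                  error = function(e) pcg_error("pcgnet_io_error",
                    sprintf("cannot open for writing: %s", path)),
                  warning = function(w) pcg_error("pcgnet_io_error",
                    sprintf("cannot open for writing: %s", path)))
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(signal$fs), con, size = 4, endian = "little")
  writeBin(as.integer(signal$fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Resample a signal to a target rate
#'
#' Band-limited polyphase resampling (anti-aliased per the Nyquist criterion).
#' The canonical pipeline rate is 2000 Hz. Output length is
#' `round(length * target_fs / fs)`, so duration is preserved to within one
#' output sample.
#'
#' @param signal An [audio_signal].
#' @param target_fs Target sampling rate in Hz.
#' @return An [audio_signal] at `target_fs`; label and source preserved.
#' @export
resample_signal <- function(signal, target_fs) {
  stopifnot(inherits(signal, "audio_signal"))
  pcg_assert(is.numeric(target_fs) && length(target_fs) == 1 && target_fs > 0,
             "pcgnet_validation_error", "target_fs must be positive")
  if (isTRUE(all.equal(target_fs, signal$fs))) return(signal)
  target_len <- round(length(signal$samples) * target_fs / signal$fs)
  pq <- rational_approx(target_fs / signal$fs, max_den = 10000L)
  y <- signal::resample(signal$samples, p = pq["p"], q = pq["q"])
  y <- as.numeric(y)
  if (length(y) >= target_len) y <- y[seq_len(target_len)]
  else y <- c(y, rep(0, target_len - length(y)))
  audio_signal(y, fs = target_fs, source_id = signal$source_id,
               label = signal$label)
}
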