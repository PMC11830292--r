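# Shared fixtures, all built in code.

make_sine <- function(freq, fs = 2000, dur = 1, amp = 1, label = NULL,
                      source_id = paste0("sine", freq)) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  audio_signal(amp * sin(2 * pi * freq * t), fs = fs, source_id = source_id,
               label = label)
}

# FFT peak frequency of a numeric vector (one-sided, excludes DC).
fft_peak_hz <- function(x, fs) {
  n <- length(x)
  mag <- Mod(stats::fft(x))[2:floor(n / 2)]
  which.max(mag) * fs / n
}

# A dataset of random labeled segments; source ids are singletons unless
# segs_per_source > 1.
make_dataset <- function(n_normal, n_abnormal, len = 32, fs = 2000,
                         segs_per_source = 1, seed = 1) {
  labels <- rep(c("normal", "abnormal"), c(n_normal, n_abnormal))
  withr::with_seed(seed, {
    segs <- lapply(seq_along(labels), function(i) {
      pcg_segment(stats::rnorm(len), fs = fs, label = labels[i],
                  source_id = sprintf("%s_src%03d", labels[i],
                                      ceiling(i / segs_per_source)),
                  start_s = 0)
    })
  })
  pcg_dataset(segs)
}

# Tiny model configuration for fast training tests.
tiny_model_config <- function(input_len = 64, head = "softmax2", seed = 7,
                              dropout = TRUE) {
  model_config(input_len = input_len, conv_filters = c(8L, 8L),
               kernel_size = 3L, pool_size = 2L,
               conv_dropout = if (dropout) 0.25 else 0,
               dense_units = 16L,
               dense_dropout = if (dropout) 0.5 else 0,
               head = head, seed = seed)
}

# Hand-rolled WAV writers for dialects write_wav does not emit (test inputs).
write_wav_raw <- function(path, frames, fs, bits = 16, format = 1L) {
  channels <- if (is.matrix(frames)) nrow(frames) else 1L
  x <- as.numeric(frames) # interleaved if matrix (channels x n, column-major)
  bytes <- bits %/% 8
  n_bytes <- length(x) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(format), con, size = 2, endian = "little")
  writeBin(as.integer(channels), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * channels * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(channels * bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  if (format == 1L) writeBin(as.integer(round(x * 32767)), con, size = 2,
                             endian = "little")
  else writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}

rms <- function(x) sqrt(mean(x^2))
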