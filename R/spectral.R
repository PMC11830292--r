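# Spectrograms and band-energy summaries (QC and augmentation verification).

#' Short-time Fourier magnitude spectrogram
#'
#' Hanning-windowed STFT magnitudes. Defaults (25 ms window, 50 % overlap)
#' sit at the midpoints of the 20-50 ms / 50-75 % ranges appropriate for
#' heart-sound transients.
#'
#' @param signal An [audio_signal].
#' @param window_ms Window length in milliseconds (5-200).
#' @param overlap_frac Fractional window overlap in `[0, 0.95]`.
#' @return A `pcg_spectrogram` with fields `magnitudes` (frequency x time,
#'   non-negative), `freqs` (Hz), `times` (s), `window_ms`, `overlap_frac`.
#' @export
spectrogram <- function(signal, window_ms = 25, overlap_frac = 0.5) {
  stopifnot(inherits(signal, "audio_signal"))
  pcg_assert(window_ms >= 5 && window_ms <= 200, "pcgnet_validation_error",
             "window_ms must lie in [5, 200]")
  pcg_assert(overlap_frac >= 0 && overlap_frac <= 0.95,
             "pcgnet_validation_error", "overlap_frac must lie in [0, 0.95]")
  wlen <- round(window_ms * signal$fs / 1000)
  pcg_assert(wlen <= length(signal$samples), "pcgnet_validation_error",
             sprintf("window (%d samples) longer than signal (%d samples)",
                     wlen, length(signal$samples)))
  n_overlap <- min(wlen - 1, round(wlen * overlap_frac))
  sg <- signal::specgram(signal$samples, n = wlen, Fs = signal$fs,
                         window = signal::hanning(wlen), overlap = n_overlap)
  structure(list(magnitudes = Mod(sg$S), freqs = as.numeric(sg$f),
                 times = as.numeric(sg$t), window_ms = window_ms,
                 overlap_frac = overlap_frac),
            class = "pcg_spectrogram")
}

#' @export
print.pcg_spectrogram <- function(x, ...) {
  cat(sprintf("<pcg_spectrogram> %d freq bins x %d frames, window %g ms, overlap %g\n",
              nrow(x$magnitudes), ncol(x$magnitudes), x$window_ms,
              x$overlap_frac))
  invisible(x)
}

#' Plot a spectrogram
#' @param x A `pcg_spectrogram`.
#' @param y Unused.
#' @param ... Passed to [graphics::image()].
#' @export
plot.pcg_spectrogram <- function(x, y, ...) {
  graphics::image(x$times, x$freqs, t(log10(x$magnitudes + 1e-12)),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' One-sided periodogram of a signal
#'
#' Power is normalized so the total equals the time-domain mean-square power
#' (Parseval).
#'
#' @param signal An [audio_signal].
#' @return List with `freqs` (Hz, 0..fs/2) and `power`.
#' @export
periodogram_power <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  n <- length(x)
  X <- stats::fft(x)
  p_full <- Mod(X)^2 / n^2
  half <- floor(n / 2)
  idx <- seq_len(half + 1)                 # bins 0 .. n/2
  power <- p_full[idx]
  if (n %% 2 == 0) {
    power[2:half] <- power[2:half] * 2     # Nyquist bin not doubled
  } else if (half >= 1) {
    power[2:(half + 1)] <- power[2:(half + 1)] * 2
  }
  list(freqs = (idx - 1) * signal$fs / n, power = power)
}

#' Fraction of spectral power in a frequency band
#'
#' Used to quantify murmur energy (e.g. the 250-350 Hz region) and to verify
#' the spectral effect of pitch-shifting.
#'
#' @param signal An [audio_signal].
#' @param f_lo,f_hi Band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @return Fraction in `[0, 1]` of total periodogram power inside
#'   `[f_lo, f_hi]`.
#' @export
band_energy_fraction <- function(signal, f_lo, f_hi) {
  stopifnot(inherits(signal, "audio_signal"))
  pcg_assert(f_lo >= 0 && f_lo < f_hi && f_hi <= signal$fs / 2,
             "pcgnet_validation_error",
             sprintf("invalid band [%g, %g] at fs = %g", f_lo, f_hi, signal$fs))
  pg <- periodogram_power(signal)
  total <- sum(pg$power)
  if (total == 0) return(0)
  in_band <- pg$freqs >= f_lo & pg$freqs <= f_hi
  sum(pg$power[in_band]) / total
}
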