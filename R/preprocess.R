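# Band-pass filtering and amplitude normalization.

#' Band-pass filter specification
#'
#' @param f_low,f_high Passband edges in Hz (`0 < f_low < f_high`).
#' @param order Prototype filter order (the band-pass has `2 * order` poles;
#'   each skirt rolls off at `6 * order` dB/octave).
#' @param design Filter family; only `"butterworth"` (maximally flat passband,
#'   -3 dB at each edge) is implemented.
#' @return A `filter_spec` object.
#' @seealso [filter_preset()] for the two passbands used by the pipeline.
#' @export
filter_spec <- function(f_low, f_high, order = 4L, design = "butterworth") {
  pcg_assert(is.numeric(f_low) && is.numeric(f_high) && f_low > 0 &&
               f_high > f_low, "pcgnet_validation_error",
             "need 0 < f_low < f_high")
  pcg_assert(order >= 1 && order == round(order), "pcgnet_validation_error",
             "order must be a positive integer")
  design <- match.arg(design, "butterworth")
  structure(list(f_low = f_low, f_high = f_high, order = as.integer(order),
                 design = design), class = "filter_spec")
}

#' Named filter presets
#'
#' Two passbands are in clinical use for heart sounds here: `"physio"`,
#' a 20-500 Hz 4th-order Butterworth (the pipeline default, matched to the
#' frequency content of pediatric S1/S2 and murmurs), and `"audacity"`,
#' a 60-650 Hz band with 48 dB/octave roll-off (order 8), matching an
#' audio-editor workflow.
#'
#' @param name `"physio"` or `"audacity"`.
#' @return A [filter_spec].
#' @export
filter_preset <- function(name = c("physio", "audacity")) {
  name <- match.arg(name)
  switch(name,
         physio = filter_spec(20, 500, order = 4L),
         audacity = filter_spec(60, 650, order = 8L))
}

#' Design digital Butterworth band-pass coefficients
#'
#' @param spec A [filter_spec].
#' @param fs Sampling rate the filter will run at, in Hz. `f_high` must be
#'   below `fs/2`, otherwise the 500 Hz edge would silently alias at low
#'   rates.
#' @return A `bandpass_coefficients` object with numerator `b`, denominator
#'   `a`, and the design context.
#' @export
design_bandpass <- function(spec, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  pcg_assert(spec$f_high < fs / 2, "pcgnet_validation_error",
             sprintf("f_high = %g Hz must be below the Nyquist rate %g Hz",
                     spec$f_high, fs / 2))
  bt <- signal::butter(spec$order, c(spec$f_low, spec$f_high) * 2 / fs,
                       type = "pass")
  structure(list(b = bt$b, a = bt$a, spec = spec, fs = fs),
            class = "bandpass_coefficients")
}

#' Magnitude response of filter coefficients
#'
#' Evaluates |H(e^{i 2 pi f / fs})| at the requested frequencies (single
#' forward pass; zero-phase application squares this response).
#'
#' @param coef A `bandpass_coefficients` object.
#' @param freqs Frequencies in Hz.
#' @return Numeric vector of magnitude gains.
#' @export
filter_response <- function(coef, freqs) {
  stopifnot(inherits(coef, "bandpass_coefficients"))
  w <- 2 * pi * freqs / coef$fs
  z <- exp(-1i * w)
  num <- sapply(z, function(zz) sum(coef$b * zz^(seq_along(coef$b) - 1)))
  den <- sapply(z, function(zz) sum(coef$a * zz^(seq_along(coef$a) - 1)))
  Mod(num / den)
}

# Zero-phase (forward-backward) IIR filtering with odd-reflection edge
# padding, so short tone bursts keep their timing and edge transients do not
# leak into the analysis window.
filtfilt_padded <- function(b, a, x) {
  n_pad <- min(length(x) - 1, 3 * (max(length(a), length(b)) - 1) * 2)
  if (n_pad > 0) {
    pre <- 2 * x[1] - x[seq(n_pad + 1, 2)]
    post <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - n_pad)]
    xp <- c(pre, x, post)
  } else xp <- x
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y <- as.numeric(y)
  if (n_pad > 0) y <- y[(n_pad + 1):(n_pad + length(x))]
  y
}

#' Apply a zero-phase Butterworth band-pass to a signal
#'
#' The filter is run forward and backward (two passes), which cancels phase
#' distortion so the timing of S1/S2 transients is preserved; the effective
#' magnitude response is the square of the single-pass response, i.e. -6 dB
#' at the passband edges.
#'
#' @param signal An [audio_signal], longer than 3x the filter order.
#' @param spec A [filter_spec]; default is the `"physio"` preset
#'   (20-500 Hz, order 4).
#' @return Filtered [audio_signal] of identical length and rate; label and
#'   source preserved.
#' @export
bandpass_filter <- function(signal, spec = filter_preset("physio")) {
  stopifnot(inherits(signal, "audio_signal"))
  pcg_assert(length(signal$samples) > 3 * spec$order,
             "pcgnet_validation_error",
             sprintf("signal too short to filter: %d samples for order %d",
                     length(signal$samples), spec$order))
  coef <- design_bandpass(spec, signal$fs)
  y <- filtfilt_padded(coef$b, coef$a, signal$samples)
  audio_signal(y, fs = signal$fs, source_id = signal$source_id,
               label = signal$label)
}

#' Peak-normalize a signal
#'
#' Rescales so that `max(abs(samples)) == 1`. Peak (not z-score) scaling is
#' used so that zero padding remains exactly zero. An all-zero signal is
#' returned unchanged with a warning and attribute `degenerate = TRUE`.
#'
#' @param signal An [audio_signal].
#' @return Normalized [audio_signal].
#' @export
normalize_signal <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  peak <- max(abs(signal$samples))
  if (peak == 0) {
    warning("all-zero signal cannot be peak-normalized; returned unchanged")
    out <- signal
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  audio_signal(signal$samples / peak, fs = signal$fs,
               source_id = signal$source_id, label = signal$label)
}
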