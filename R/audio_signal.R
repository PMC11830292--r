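#' Construct a heart-sound audio signal
#'
#' The basic container flowing through the preprocessing chain: a mono sampled
#' waveform with its sampling rate, an identifier for the source recording and
#' an optional class label.
#'
#' @param samples Numeric vector of amplitudes, nominally in \[-1, 1\].
#' @param fs Sampling rate in Hz (positive).
#' @param source_id Opaque identifier of the source recording.
#' @param label Optional class label, one of `"normal"` or `"abnormal"`.
#' @return An object of class `audio_signal` with fields `samples`, `fs`,
#'   `source_id`, `label`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 100 * seq(0, 1, by = 1/2000)), fs = 2000)
#' signal_duration(s)
#' @export
audio_signal <- function(samples, fs, source_id = "signal", label = NULL) {
  pcg_assert(is.numeric(fs) && length(fs) == 1 && fs > 0,
             "pcgnet_validation_error", "fs must be a positive scalar")
  pcg_assert(is.numeric(samples) && length(samples) >= 1,
             "pcgnet_validation_error", "samples must be a non-empty numeric vector")
  if (!is.null(label)) {
    pcg_assert(label %in% c("normal", "abnormal"), "pcgnet_validation_error",
               sprintf("label must be 'normal' or 'abnormal', got '%s'", label))
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 source_id = as.character(source_id), label = label),
            class = "audio_signal")
}

#' Duration of a signal in seconds
#' @param signal An `audio_signal`.
#' @return `length(samples) / fs`, in seconds.
#' @export
signal_duration <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  length(signal$samples) / signal$fs
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %s: %d samples @ %g Hz (%.3f s)%s\n",
              x$source_id, length(x$samples), x$fs,
              signal_duration(x),
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}
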