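# Fixed-length windowing of recordings into model-ready segments.

#' Construct a labeled segment
#'
#' The unit of model input: a fixed-length window cut from a recording.
#'
#' @param samples Numeric vector of fixed length.
#' @param fs Sampling rate in Hz.
#' @param label `"normal"` or `"abnormal"`.
#' @param source_id Identifier of the source recording (used for grouped
#'   train/test splitting).
#' @param start_s Offset of the window within the recording, in seconds.
#' @param augmented Whether the segment was produced by augmentation.
#' @return A `pcg_segment` object.
#' @export
pcg_segment <- function(samples, fs, label, source_id = "segment",
                        start_s = 0, augmented = FALSE) {
  pcg_assert(start_s >= 0, "pcgnet_validation_error", "start_s must be >= 0")
  pcg_assert(label %in% c("normal", "abnormal"), "pcgnet_validation_error",
             "segment label must be 'normal' or 'abnormal'")
  structure(list(samples = as.numeric(samples), fs = fs, label = label,
                 source_id = as.character(source_id), start_s = start_s,
                 augmented = isTRUE(augmented)),
            class = "pcg_segment")
}

#' Pad a sample vector to a target length
#'
#' `"wrap"` repeats the input cyclically, exploiting the periodicity of
#' cardiac cycles so a padded window still looks like heart sound; `"zero"`
#' appends silence.
#'
#' @param samples Numeric vector, no longer than `target_len`.
#' @param target_len Required output length.
#' @param mode `"wrap"` (default) or `"zero"`.
#' @return Numeric vector of length `target_len`.
#' @examples
#' pad_segment(c(1, 2, 3), 7, "wrap") # 1 2 3 1 2 3 1
#' @export
pad_segment <- function(samples, target_len, mode = c("wrap", "zero")) {
  mode <- match.arg(mode)
  n <- length(samples)
  pcg_assert(n >= 1, "pcgnet_validation_error", "samples must be non-empty")
  pcg_assert(n <= target_len, "pcgnet_validation_error",
             sprintf("input length %d exceeds target length %d", n, target_len))
  if (n == target_len) return(samples)
  if (mode == "wrap") rep(samples, length.out = target_len)
  else c(samples, rep(0, target_len - n))
}

#' Cut a recording into fixed-length segments
#'
#' Windows of `round(seg_seconds * fs)` samples are taken at hop
#' `seg_seconds * (1 - overlap_frac)`; a trailing partial window is padded to
#' full length. The number of segments is
#' `max(1, ceiling((duration - seg_seconds) / hop) + 1)`.
#'
#' @param signal A labeled [audio_signal].
#' @param seg_seconds Window length in seconds (default 4, the clinical
#'   chunk length; 8 s matches the alternative whole-record input).
#' @param overlap_frac Fractional overlap between consecutive windows, in
#'   `[0, 1)`. Default 0 (disjoint chunks).
#' @param pad_mode Padding mode for the final partial window, see
#'   [pad_segment()].
#' @return List of [pcg_segment] objects inheriting the signal's label.
#' @export
segment_signal <- function(signal, seg_seconds = 4, overlap_frac = 0,
                           pad_mode = c("wrap", "zero")) {
  stopifnot(inherits(signal, "audio_signal"))
  pad_mode <- match.arg(pad_mode)
  pcg_assert(seg_seconds > 0, "pcgnet_validation_error",
             "seg_seconds must be positive")
  pcg_assert(overlap_frac >= 0 && overlap_frac < 1, "pcgnet_validation_error",
             "overlap_frac must lie in [0, 1)")
  pcg_assert(!is.null(signal$label), "pcgnet_validation_error",
             "signal must carry a label before segmentation")
  dur <- signal_duration(signal)
  hop <- seg_seconds * (1 - overlap_frac)
  n_seg <- max(1, ceiling((dur - seg_seconds) / hop - 1e-9) + 1)
  seg_len <- round(seg_seconds * signal$fs)
  n <- length(signal$samples)
  lapply(seq_len(n_seg) - 1, function(i) {
    start_s <- i * hop
    from <- round(start_s * signal$fs) + 1
    to <- min(n, from + seg_len - 1)
    chunk <- signal$samples[from:to]
    if (length(chunk) < seg_len) chunk <- pad_segment(chunk, seg_len, pad_mode)
    pcg_segment(chunk, fs = signal$fs, label = signal$label,
                source_id = signal$source_id, start_s = start_s)
  })
}
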