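# Pitch-shift augmentation and class balancing.

#' Pitch-shift a segment
#'
#' Scales every spectral component from frequency `f` to `f * factor` while
#' preserving duration: the samples are polyphase-resampled by `1/factor`
#' (time compression/expansion) and then wrap-padded or trimmed back to the
#' original length. The default factor `800/650` widens heart-sound content
#' from the 60-650 Hz band up to 60-800 Hz.
#'
#' @param segment A [pcg_segment].
#' @param factor Positive frequency-scaling ratio.
#' @param content_f_high Assumed highest content frequency in Hz, used for the
#'   aliasing guard: `content_f_high * factor` must stay below `fs/2`.
#' @return A [pcg_segment] of identical length and rate with `augmented = TRUE`.
#' @export
pitch_shift <- function(segment, factor = 800 / 650, content_f_high = 650) {
  stopifnot(inherits(segment, "pcg_segment"))
  pcg_assert(factor > 0, "pcgnet_validation_error", "factor must be positive")
  pcg_assert(content_f_high * factor < segment$fs / 2,
             "pcgnet_validation_error",
             sprintf(paste0("pitch factor %.4g would alias: %g Hz content ",
                            "maps to %g Hz >= Nyquist %g Hz"),
                     factor, content_f_high, content_f_high * factor,
                     segment$fs / 2))
  n <- length(segment$samples)
  if (isTRUE(all.equal(factor, 1))) {
    y <- segment$samples
  } else {
    pq <- rational_approx(1 / factor, max_den = 4096L)
    y <- as.numeric(signal::resample(segment$samples, p = pq["p"], q = pq["q"]))
    if (length(y) >= n) y <- y[seq_len(n)]
    else y <- pad_segment(y, n, mode = "wrap")
  }
  out <- segment
  out$samples <- y
  out$augmented <- TRUE
  out
}

#' Balance class counts by augmenting the minority class
#'
#' Minority-class segments are pitch-shifted with factors drawn (seeded) from
#' `pitch_factors` and appended until the two classes are equally represented.
#' Originals are never removed.
#'
#' @param dataset A [pcg_dataset].
#' @param policy Balancing policy; only `"augment_minority"` is implemented.
#' @param pitch_factors Pool of frequency ratios to draw from. The defaults
#'   shift content up to the 800 Hz ceiling and down by the inverse ratio.
#' @param seed Integer seed for the factor/segment draws.
#' @return A balanced [pcg_dataset].
#' @export
balance_classes <- function(dataset, policy = "augment_minority",
                            pitch_factors = c(800 / 650, 650 / 800),
                            seed = 1L) {
  stopifnot(inherits(dataset, "pcg_dataset"))
  policy <- match.arg(policy, "augment_minority")
  cc <- class_counts(dataset)
  pcg_assert(all(cc >= 1), "pcgnet_validation_error",
             sprintf("both classes need at least one segment, got normal=%d abnormal=%d",
                     cc["normal"], cc["abnormal"]))
  if (cc["normal"] == cc["abnormal"]) return(dataset)
  minority <- if (cc["normal"] < cc["abnormal"]) "normal" else "abnormal"
  deficit <- abs(cc["normal"] - cc["abnormal"])
  pool <- Filter(function(s) s$label == minority, dataset$segments)
  new_segs <- with_local_seed(seed, {
    src_idx <- sample(rep_len(seq_along(pool), deficit))
    factors <- sample(pitch_factors, deficit, replace = TRUE)
    lapply(seq_len(deficit), function(i)
      pitch_shift(pool[[src_idx[i]]], factor = factors[i]))
  })
  pcg_dataset(c(dataset$segments, new_segs))
}
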