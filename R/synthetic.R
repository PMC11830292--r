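# Synthetic phonocardiogram generator: periodic S1/S2 valve-closure
# transients, broadband background noise, and (for the abnormal class) a
# band-limited systolic murmur.

#' Synthetic PCG generator configuration
#'
#' Defaults model a pediatric recording setup: 2000 Hz sampling, 10-s
#' recordings, heart rate 70-140 bpm, S1 tone in 60-120 Hz, S2 in 80-160 Hz,
#' murmur noise in 250-350 Hz at 6 dB above the broadband noise floor
#' (-30 dB relative to the S1 peak).
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording length in seconds (sensible range 8-12).
#' @param heart_rate_bpm Length-2 range the per-recording heart rate is drawn
#'   from, in beats per minute.
#' @param s1_freq,s2_freq Length-2 Hz ranges the S1/S2 tone frequencies are
#'   drawn from.
#' @param murmur_band Length-2 Hz range of the murmur noise.
#' @param murmur_snr_db Murmur power above the noise floor, in dB. More
#'   negative values make the classes harder to separate.
#' @param noise_floor_db Broadband white-noise RMS relative to the unit S1
#'   peak, in dB.
#' @param seed Master seed; every waveform is fully determined by it.
#' @return A `synth_config` object.
#' @export
synth_config <- function(fs = 2000, duration_s = 10,
                         heart_rate_bpm = c(70, 140),
                         s1_freq = c(60, 120), s2_freq = c(80, 160),
                         murmur_band = c(250, 350), murmur_snr_db = 6,
                         noise_floor_db = -30, seed = 1L) {
  pcg_assert(max(s1_freq, s2_freq, murmur_band) < fs / 2,
             "pcgnet_validation_error", "all band edges must lie below fs/2")
  pcg_assert(duration_s > 2 * (60 / min(heart_rate_bpm)),
             "pcgnet_validation_error",
             "duration must cover at least two cardiac cycles")
  structure(list(fs = fs, duration_s = duration_s,
                 heart_rate_bpm = heart_rate_bpm, s1_freq = s1_freq,
                 s2_freq = s2_freq, murmur_band = murmur_band,
                 murmur_snr_db = murmur_snr_db,
                 noise_floor_db = noise_floor_db, seed = as.integer(seed)),
            class = "synth_config")
}

# Gaussian-windowed tone burst added onto x (in place semantics via return).
add_burst <- function(x, fs, t0, freq, amp, dur) {
  n <- length(x)
  from <- max(1, floor(t0 * fs) + 1)
  to <- min(n, ceiling((t0 + dur) * fs))
  if (from >= to) return(x)
  t <- (seq(from, to) - 1) / fs
  mid <- t0 + dur / 2
  env <- exp(-0.5 * ((t - mid) / (dur / 5))^2)
  x[from:to] <- x[from:to] + amp * env * sin(2 * pi * freq * (t - t0))
  x
}

#' Generate one synthetic heart-sound recording
#'
#' A normal recording is a train of cardiac cycles, each an S1 burst followed
#' by an S2 burst at systolic timing, over a white-noise floor. An abnormal
#' recording additionally carries a band-limited noise murmur filling systole
#' (between S1 and S2). Cycle lengths and burst amplitudes jitter by +-5 %;
#' the number of cycles is `round(duration_s * hr / 60)` with the jittered
#' spacings rescaled to fill the recording exactly. The waveform is fully
#' determined by `config$seed`.
#'
#' @param label `"normal"` or `"abnormal"`.
#' @param config A [synth_config].
#' @return A labeled [audio_signal]; attribute `n_cycles` records the number
#'   of cardiac cycles placed.
#' @export
generate_pcg <- function(label = c("normal", "abnormal"),
                         config = synth_config()) {
  label <- match.arg(label)
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n <- round(config$duration_s * fs)
  with_local_seed(config$seed, {
    hr <- stats::runif(1, config$heart_rate_bpm[1], config$heart_rate_bpm[2])
    f1 <- stats::runif(1, config$s1_freq[1], config$s1_freq[2])
    f2 <- stats::runif(1, config$s2_freq[1], config$s2_freq[2])
    k <- max(2, round(config$duration_s * hr / 60))
    raw <- (60 / hr) * (1 + stats::runif(k, -0.05, 0.05))
    spacing <- raw * config$duration_s / sum(raw)
    starts <- cumsum(c(0.02, spacing[-k]))
    noise_rms <- 10^(config$noise_floor_db / 20)
    x <- stats::rnorm(n, sd = noise_rms)
    murmur <- NULL
    if (label == "abnormal") {
      mn <- stats::rnorm(n)
      bp <- signal::butter(4, config$murmur_band * 2 / fs, type = "pass")
      mn <- filtfilt_padded(bp$b, bp$a, mn)
      murmur_rms <- noise_rms * 10^(config$murmur_snr_db / 20)
      murmur <- mn / stats::sd(mn) * murmur_rms
    }
    for (i in seq_len(k)) {
      t0 <- starts[i]
      period <- spacing[i]
      sys_frac <- 0.35
      a1 <- 1 * (1 + stats::runif(1, -0.05, 0.05))
      a2 <- 0.75 * (1 + stats::runif(1, -0.05, 0.05))
      x <- add_burst(x, fs, t0, f1, a1, dur = 0.07)
      x <- add_burst(x, fs, t0 + sys_frac * period, f2, a2, dur = 0.06)
      if (!is.null(murmur)) {
        g_from <- t0 + 0.07
        g_to <- t0 + sys_frac * period
        i0 <- max(1, floor(g_from * fs) + 1)
        i1 <- min(n, ceiling(g_to * fs))
        if (i1 > i0 + 3) {
          gate <- signal::hanning(i1 - i0 + 1)
          x[i0:i1] <- x[i0:i1] + murmur[i0:i1] * gate * 2
        }
      }
    }
    peak <- max(abs(x))
    if (peak > 0.95) x <- x * 0.95 / peak
    out <- audio_signal(x, fs = fs,
                        source_id = sprintf("synth_%s_%d", label, config$seed),
                        label = label)
    attr(out, "n_cycles") <- k
    out
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes mono PCM16 WAV files plus a `path,label` manifest CSV with the same
#' schema a real-data manifest uses. The per-recording seed is derived
#' deterministically from the master seed, so any single file can be
#' regenerated in isolation.
#'
#' @param n_normal,n_abnormal Recording counts per class.
#' @param config A [synth_config]; its `seed` is the master seed.
#' @param out_dir Output directory (created if missing).
#' @return The manifest data frame (columns `path`, `label`), invisibly;
#'   the manifest is written to `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(n_normal = 400L, n_abnormal = 400L,
                             config = synth_config(), out_dir) {
  pcg_assert(n_normal >= 0 && n_abnormal >= 0, "pcgnet_validation_error",
             "counts must be non-negative")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pcg_assert(dir.exists(out_dir) && file.access(out_dir, 2) == 0,
             "pcgnet_io_error", sprintf("cannot write to %s", out_dir))
  labels <- rep(c("normal", "abnormal"), c(n_normal, n_abnormal))
  rows <- lapply(seq_along(labels), function(k) {
    cfg_k <- config
    cfg_k$seed <- derive_seed(config$seed, k)
    sig <- generate_pcg(labels[k], cfg_k)
    path <- file.path(out_dir, sprintf("pcg_%s_%04d.wav", labels[k], k))
    write_wav(sig, path)
    data.frame(path = path, label = labels[k], stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows) > 0) do.call(rbind, rows)
  else data.frame(path = character(0), label = character(0))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Generate a synthetic dataset in memory
#'
#' Convenience twin of [generate_dataset()] that skips the WAV round trip:
#' returns the recordings as a list of labeled [audio_signal]s with the same
#' per-recording seed derivation (element `k` is bit-identical to the signal
#' behind file `k`).
#'
#' @inheritParams generate_dataset
#' @return List of [audio_signal] objects.
#' @export
generate_signals <- function(n_normal = 400L, n_abnormal = 400L,
                             config = synth_config()) {
  labels <- rep(c("normal", "abnormal"), c(n_normal, n_abnormal))
  lapply(seq_along(labels), function(k) {
    cfg_k <- config
    cfg_k$seed <- derive_seed(config$seed, k)
    sig <- generate_pcg(labels[k], cfg_k)
    sig$source_id <- sprintf("synth_%s_%04d", labels[k], k)
    sig
  })
}
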