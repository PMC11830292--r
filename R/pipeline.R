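# End-to-end pipeline plumbing: preprocessing chains, the full
# simulate -> preprocess -> split -> train -> evaluate experiment, and the
# text configuration shared with the command-line interface.

#' Default pipeline configuration
#'
#' A nested list of every tunable the pipeline exposes, with the package
#' defaults: `physio` band-pass (20-500 Hz, order 4), canonical rate 2000 Hz,
#' 4-s disjoint segments with wrap padding, pitch-shift augmentation of the
#' minority class, sequential 70/15/15 split, the default CNN architecture
#' and Adam training settings, and the synthetic generator defaults.
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    io = list(canonical_fs = 2000),
    filter = list(preset = "physio", f_low = NULL, f_high = NULL, order = NULL),
    segment = list(seconds = 4, overlap = 0, pad_mode = "wrap"),
    augment = list(pitch_factors = c(800 / 650, 650 / 800), seed = 1,
                   balance = TRUE),
    split = list(test_frac = 0.15, val_frac = 0.15, seed = 1,
                 method = "sequential"),
    model = list(conv_filters = c(64, 128, 128, 64, 32, 16), kernel_size = 3,
                 pool_size = 2, conv_dropout = 0.25, dense_units = 128,
                 dense_dropout = 0.5, head = "softmax2", seed = 42),
    train = list(learning_rate = 1e-3, epochs = 30, batch_size = 32, seed = 1,
                 early_stop_patience = NULL),
    synth = list(n_normal = 400, n_abnormal = 400, duration_s = 10,
                 murmur_snr_db = 6, noise_floor_db = -30, seed = 1)
  )
}

#' Load and validate a pipeline configuration file
#'
#' Reads a YAML key-value file and merges it over the defaults. Unknown
#' groups or keys are rejected with the offending key named.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(cfg)
  pcg_assert(file.exists(path), "pcgnet_io_error",
             sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  for (grp in names(user)) {
    pcg_assert(grp %in% names(cfg), "pcgnet_validation_error",
               sprintf("unknown config group: '%s'", grp))
    for (key in names(user[[grp]])) {
      pcg_assert(key %in% names(cfg[[grp]]), "pcgnet_validation_error",
                 sprintf("unknown config key: '%s.%s'", grp, key))
      cfg[[grp]][[key]] <- user[[grp]][[key]]
    }
  }
  cfg
}

config_filter_spec <- function(cfg) {
  f <- cfg$filter
  if (!is.null(f$f_low) || !is.null(f$f_high) || !is.null(f$order)) {
    base <- filter_preset(f$preset %||% "physio")
    filter_spec(f$f_low %||% base$f_low, f$f_high %||% base$f_high,
                f$order %||% base$order)
  } else filter_preset(f$preset %||% "physio")
}

#' Preprocess one recording into model-ready segments
#'
#' The default chain of the pipeline: zero-phase band-pass filter, resampling
#' to the canonical rate, peak normalization, then fixed-length segmentation.
#'
#' @param signal A labeled [audio_signal].
#' @param config Pipeline configuration list (see
#'   [default_pipeline_config()]).
#' @return List of [pcg_segment]s.
#' @export
preprocess_signal <- function(signal, config = default_pipeline_config()) {
  spec <- config_filter_spec(config)
  out <- bandpass_filter(signal, spec)
  out <- resample_signal(out, config$io$canonical_fs)
  out <- normalize_signal(out)
  segment_signal(out, seg_seconds = config$segment$seconds,
                 overlap_frac = config$segment$overlap,
                 pad_mode = config$segment$pad_mode)
}

#' Preprocess a set of recordings into a dataset
#'
#' Applies [preprocess_signal()] to each recording; recordings that raise a
#' package condition (unreadable or contentless files) are skipped and
#' reported, so one bad file does not abort a batch run.
#'
#' @param signals List of labeled [audio_signal]s, or a manifest data frame
#'   with `path`/`label` columns whose WAVs are read on the fly.
#' @param config Pipeline configuration list.
#' @return A [pcg_dataset]; attribute `skipped` lists skipped sources.
#' @export
preprocess_recordings <- function(signals, config = default_pipeline_config()) {
  skipped <- character(0)
  segs <- list()
  fetch <- if (is.data.frame(signals)) {
    function(i) read_wav(signals$path[i], label = signals$label[i])
  } else {
    function(i) signals[[i]]
  }
  n <- if (is.data.frame(signals)) nrow(signals) else length(signals)
  for (i in seq_len(n)) {
    res <- tryCatch(preprocess_signal(fetch(i), config),
                    pcgnet_error = function(e) e)
    if (inherits(res, "pcgnet_error")) {
      skipped <- c(skipped, conditionMessage(res))
    } else {
      segs <- c(segs, res)
    }
  }
  out <- pcg_dataset(segs)
  attr(out, "skipped") <- skipped
  out
}

#' Run the full desk-scale experiment
#'
#' Simulates a labeled recording set, preprocesses and segments it, performs
#' the grouped stratified 70/15/15 split, balances the training partition by
#' pitch-shift augmentation, trains the CNN and evaluates on the held-out
#' test partition. One seed drives generation, splitting, initialization and
#' training.
#'
#' @param n_normal,n_abnormal Recording counts per class.
#' @param seed Master seed for the replicate.
#' @param epochs Training epochs.
#' @param config Pipeline configuration list; `train$epochs` and all seeds
#'   are overridden by the `seed`/`epochs` arguments.
#' @param verbose Print stage progress.
#' @return List with `metrics`, `auc`, `history`, `split_sizes`, `model`,
#'   `report`.
#' @export
run_experiment <- function(n_normal = 400L, n_abnormal = 400L, seed = 1L,
                           epochs = 10L,
                           config = default_pipeline_config(),
                           verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  scfg <- synth_config(duration_s = config$synth$duration_s,
                       murmur_snr_db = config$synth$murmur_snr_db,
                       noise_floor_db = config$synth$noise_floor_db,
                       seed = derive_seed(seed, 1))
  say("simulating %d + %d recordings (seed %d)", n_normal, n_abnormal, seed)
  signals <- generate_signals(n_normal, n_abnormal, scfg)
  say("preprocessing %d recordings", length(signals))
  dataset <- preprocess_recordings(signals, config)
  split <- split_dataset(dataset, config$split$test_frac,
                         config$split$val_frac,
                         seed = derive_seed(seed, 2),
                         method = config$split$method)
  train_set <- if (isTRUE(config$augment$balance))
    balance_classes(split$train, pitch_factors = config$augment$pitch_factors,
                    seed = derive_seed(seed, 3))
  else split$train
  seg_len <- length(dataset$segments[[1]]$samples)
  mcfg <- model_config(input_len = seg_len,
                       conv_filters = config$model$conv_filters,
                       kernel_size = config$model$kernel_size,
                       pool_size = config$model$pool_size,
                       conv_dropout = config$model$conv_dropout,
                       dense_units = config$model$dense_units,
                       dense_dropout = config$model$dense_dropout,
                       head = config$model$head,
                       seed = derive_seed(seed, 4))
  model <- build_model(mcfg)
  tcfg <- train_config(learning_rate = config$train$learning_rate,
                       epochs = epochs,
                       batch_size = config$train$batch_size,
                       seed = derive_seed(seed, 5),
                       early_stop_patience = config$train$early_stop_patience)
  say("training %d epochs on %d segments", epochs,
      length(train_set$segments))
  model <- train_model(model, train_set, split$val, tcfg)
  report <- evaluate_model(model, split$test)
  say("held-out accuracy %.3f, AUC %.3f", report$metrics$accuracy, report$auc)
  list(metrics = report$metrics, auc = report$auc, history = model$history,
       split_sizes = split$sizes, model = model, report = report)
}
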