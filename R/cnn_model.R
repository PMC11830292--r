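# The customized 1-D CNN: stacked conv/batch-norm/ReLU/max-pool/dropout
# blocks, a dense layer and a probabilistic head.

#' Configure the 1-D CNN architecture
#'
#' The default reconciles the two printed variants of the network: 6 blocks
#' of `conv(kernel 3, same padding) -> batch norm -> ReLU -> max-pool(2) ->
#' dropout(0.25)` with filter counts (64, 128, 128, 64, 32, 16), followed by
#' `flatten -> dense(128) -> ReLU -> dropout(0.5) -> head`. The head is a
#' 2-way softmax by default (matching the categorical cross-entropy loss);
#' a single sigmoid unit emitting P(abnormal) is selectable.
#'
#' @param input_len Segment length in samples. Must be divisible by
#'   `pool_size ^ n_blocks` (pooling alone controls the time length).
#'   Default 8000 = 4 s at the canonical 2000 Hz; 16,000 fits 8-s segments.
#' @param conv_filters Filter counts per block; its length sets the number of
#'   blocks.
#' @param kernel_size Convolution kernel width (default 3).
#' @param pool_size Max-pool width/stride (default 2).
#' @param conv_dropout Dropout rate after each pooled block (default 0.25).
#' @param dense_units Width of the fully connected layer (default 128).
#' @param dense_dropout Dropout rate after the dense layer (default 0.5).
#' @param head `"softmax2"` (two probabilities summing to 1) or `"sigmoid1"`
#'   (single P(abnormal)).
#' @param seed Seed for weight initialization.
#' @return A `model_config` object.
#' @export
model_config <- function(input_len = 8000L,
                         conv_filters = c(64L, 128L, 128L, 64L, 32L, 16L),
                         kernel_size = 3L, pool_size = 2L,
                         conv_dropout = 0.25, dense_units = 128L,
                         dense_dropout = 0.5,
                         head = c("softmax2", "sigmoid1"), seed = 42L) {
  head <- match.arg(head)
  n_blocks <- length(conv_filters)
  pcg_assert(kernel_size >= 1, "pcgnet_validation_error", "kernel_size must be >= 1")
  pcg_assert(pool_size >= 1, "pcgnet_validation_error", "pool_size must be >= 1")
  pcg_assert(conv_dropout >= 0 && conv_dropout < 1 &&
               dense_dropout >= 0 && dense_dropout < 1,
             "pcgnet_validation_error", "dropout rates must lie in [0, 1)")
  divisor <- pool_size^n_blocks
  pcg_assert(input_len %% divisor == 0, "pcgnet_validation_error",
             sprintf("input_len %d is not divisible by pool_size^n_blocks = %d^%d = %d",
                     input_len, pool_size, n_blocks, divisor))
  structure(list(input_len = as.integer(input_len),
                 conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 n_blocks = n_blocks,
                 conv_dropout = conv_dropout,
                 dense_units = as.integer(dense_units),
                 dense_dropout = dense_dropout,
                 head = head, seed = as.integer(seed)),
            class = "model_config")
}

#' Shape algebra of a model configuration
#'
#' @param config A [model_config].
#' @return List with `time_steps` (time length after the last pool; equals
#'   `input_len / pool_size^n_blocks`), `flat_len` (flattened feature length
#'   = time_steps x last filter count) and `n_out` (head width).
#' @export
model_shape <- function(config) {
  stopifnot(inherits(config, "model_config"))
  ts <- config$input_len %/% config$pool_size^config$n_blocks
  list(time_steps = ts,
       flat_len = ts * config$conv_filters[config$n_blocks],
       n_out = if (config$head == "softmax2") 2L else 1L)
}

# Seeded uniform fan-in initialization for one weight matrix.
init_mat <- function(n_out, n_in) {
  lim <- sqrt(6 / n_in)
  matrix(stats::runif(n_out * n_in, -lim, lim), nrow = n_out)
}

#' Build an (untrained) model from a configuration
#'
#' Weights are drawn from a seeded uniform fan-in scheme; batch-norm scales
#' start at 1, shifts at 0, running statistics at (0, 1).
#'
#' @param config A [model_config].
#' @return A `pcg_cnn` object with fields `config`, `params`, `history`,
#'   `trained`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  shape <- model_shape(config)
  params <- with_local_seed(config$seed, {
    in_ch <- 1L
    conv <- lapply(seq_len(config$n_blocks), function(l) {
      f <- config$conv_filters[l]
      w <- init_mat(f, in_ch * config$kernel_size)
      in_ch <<- f
      list(W = w, b = numeric(f), gamma = rep(1, f), beta = numeric(f),
           rmean = numeric(f), rvar = rep(1, f))
    })
    list(conv = conv,
         dense = list(W = init_mat(config$dense_units, shape$flat_len),
                      b = numeric(config$dense_units)),
         head = list(W = init_mat(shape$n_out, config$dense_units),
                     b = numeric(shape$n_out)))
  })
  structure(list(config = config, params = params, history = NULL,
                 trained = FALSE),
            class = "pcg_cnn")
}

#' @export
print.pcg_cnn <- function(x, ...) {
  cat(sprintf("<pcg_cnn> input %d, blocks (%s), kernel %d, pool %d, dense %d, head %s%s\n",
              x$config$input_len, paste(x$config$conv_filters, collapse = ", "),
              x$config$kernel_size, x$config$pool_size, x$config$dense_units,
              x$config$head, if (x$trained) " [trained]" else " [untrained]"))
  invisible(x)
}

#' Numerically stable softmax
#'
#' Invariant to adding a constant to all logits; computed in shifted form.
#'
#' @param logits Numeric vector, or matrix with one row per sample.
#' @return Probabilities of the same shape; each vector/row is positive and
#'   sums to 1.
#' @export
softmax <- function(logits) {
  pcg_assert(all(is.finite(logits)), "pcgnet_validation_error",
             "logits must be finite")
  if (is.matrix(logits)) {
    z <- logits - apply(logits, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    e <- exp(logits - max(logits))
    e / sum(e)
  }
}

# Stack segments into an (input_len x n) matrix, validating lengths.
segments_matrix <- function(segments, input_len) {
  if (inherits(segments, "pcg_dataset")) segments <- segments$segments
  if (inherits(segments, "pcg_segment")) segments <- list(segments)
  lens <- vapply(segments, function(s) length(s$samples), integer(1))
  bad <- which(lens != input_len)
  if (length(bad) > 0)
    pcg_error("pcgnet_validation_error",
              sprintf("segment length mismatch: model expects %d samples, got %d",
                      input_len, lens[bad[1]]))
  vapply(segments, `[[`, numeric(input_len), "samples")
}

#' Forward pass: class probabilities for a batch of segments
#'
#' Inference is deterministic: dropout is inactive and batch normalization
#' uses running statistics.
#'
#' @param model A `pcg_cnn`.
#' @param segments A [pcg_dataset], a list of [pcg_segment], or one segment.
#' @param batch_size Segments per compute chunk (memory control only;
#'   results are independent of it).
#' @return Numeric matrix, one row per segment: columns `normal`/`abnormal`
#'   for a softmax head (rows sum to 1), single column `abnormal` for a
#'   sigmoid head.
#' @export
model_forward <- function(model, segments, batch_size = 64L) {
  stopifnot(inherits(model, "pcg_cnn"))
  X <- segments_matrix(segments, model$config$input_len)
  n <- ncol(X)
  shape <- model_shape(model$config)
  out <- matrix(NA_real_, nrow = n, ncol = shape$n_out)
  for (from in seq(1, n, by = batch_size)) {
    to <- min(n, from + batch_size - 1)
    p <- .cnn_forward_cpp(model$params, unclass(model$config),
                          X[, from:to, drop = FALSE])
    out[from:to, ] <- t(p)
  }
  colnames(out) <- if (shape$n_out == 2) c("normal", "abnormal") else "abnormal"
  out
}

#' Probability of the abnormal class per segment
#' @param probs Output of [model_forward()].
#' @return Numeric vector of P(abnormal).
#' @keywords internal
prob_abnormal <- function(probs) {
  probs[, "abnormal"]
}

#' @rdname model_forward
#' @param object A `pcg_cnn`.
#' @param type `"prob"` for class probabilities, `"label"` for hard labels at
#'   the 0.5 threshold.
#' @param ... Unused.
#' @export
predict.pcg_cnn <- function(object, segments, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  p <- model_forward(object, segments)
  if (type == "prob") return(p)
  ifelse(prob_abnormal(p) > 0.5, "abnormal", "normal")
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single self-describing archive holding the
#' configuration, learned parameters and training history, with a format
#' version field.
#'
#' @param model A `pcg_cnn`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `pcg_cnn` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pcg_cnn"))
  saveRDS(list(format = "pcgnet_checkpoint", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  pcg_assert(identical(obj$format, "pcgnet_checkpoint"),
             "pcgnet_format_error", "not a pcgnet checkpoint")
  obj$model
}
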