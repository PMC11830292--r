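# Mini-batch Adam training on the cross-entropy loss.

#' Training configuration
#'
#' @param learning_rate Adam step size eta (default 1e-3).
#' @param epochs Number of passes over the training set (default 30).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Seed controlling shuffling, dropout and any augmentation draw.
#' @param early_stop_patience Stop after this many epochs without a new best
#'   validation loss and return the best-epoch weights; `NULL` disables early
#'   stopping (final-epoch weights are returned).
#' @param beta1,beta2,eps Adam moment decays and stabilizer
#'   (defaults 0.9 / 0.999 / 1e-8).
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 30L, batch_size = 32L,
                         seed = 1L, early_stop_patience = NULL,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  pcg_assert(learning_rate >= 0, "pcgnet_validation_error",
             "learning_rate must be non-negative")
  pcg_assert(epochs >= 1, "pcgnet_validation_error", "epochs must be >= 1")
  pcg_assert(batch_size >= 1, "pcgnet_validation_error", "batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 early_stop_patience = early_stop_patience,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

#' Binary cross-entropy loss
#'
#' Mean over segments of `-(y log p + (1 - y) log(1 - p))`, with predictions
#' clipped to `[1e-7, 1 - 1e-7]` before the log. For two-column probability
#' matrices the abnormal-class column is used (for one-hot labels and a
#' softmax head this equals the categorical cross-entropy).
#'
#' @param y_true 0/1 vector (1 = abnormal), or labels
#'   `"normal"`/`"abnormal"`, or a two-column one-hot matrix.
#' @param y_prob P(abnormal) per segment, or a two-column probability matrix.
#' @return Non-negative mean loss.
#' @export
cross_entropy <- function(y_true, y_prob) {
  if (is.matrix(y_true)) y_true <- y_true[, ncol(y_true)]
  if (is.character(y_true) || is.factor(y_true))
    y_true <- as.integer(as.character(y_true) == "abnormal")
  if (is.matrix(y_prob)) y_prob <- y_prob[, ncol(y_prob)]
  pcg_assert(length(y_true) == length(y_prob), "pcgnet_validation_error",
             sprintf("length mismatch: %d labels vs %d predictions",
                     length(y_true), length(y_prob)))
  eps <- 1e-7
  p <- pmin(pmax(y_prob, eps), 1 - eps)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}

# Flattened views of the trainable parameter slots, for the Adam update.
param_slots <- function(params) {
  slots <- list()
  for (l in seq_along(params$conv))
    for (f in c("W", "b", "gamma", "beta"))
      slots[[length(slots) + 1]] <- list(c("conv", l, f))
  for (f in c("W", "b")) slots[[length(slots) + 1]] <- list(c("dense", f))
  for (f in c("W", "b")) slots[[length(slots) + 1]] <- list(c("head", f))
  lapply(slots, `[[`, 1)
}

get_slot <- function(x, path) {
  for (p in path) x <- x[[if (grepl("^[0-9]+$", p)) as.integer(p) else p]]
  x
}

set_slot <- function(x, path, value) {
  if (length(path) == 1) {
    x[[if (grepl("^[0-9]+$", path)) as.integer(path) else path]] <- value
    return(x)
  }
  key <- if (grepl("^[0-9]+$", path[1])) as.integer(path[1]) else path[1]
  x[[key]] <- set_slot(x[[key]], path[-1], value)
  x
}

# Re-estimate the batch-norm running statistics with a dropout-free pass
# over the training matrix: each layer's running mean/variance is set to the
# batch-size-weighted average of its batch statistics. An exponential moving
# average lags badly at small step counts; this removes the lag so
# inference-mode behavior matches training-mode behavior.
recalibrate_bn <- function(model, X, batch_size, max_segments = 128L) {
  if (ncol(X) > max_segments) {
    # deterministic, evenly spaced subsample; each segment contributes one
    # statistic per channel per time step, so this is still thousands of
    # observations per channel
    X <- X[, unique(round(seq(1, ncol(X), length.out = max_segments))),
           drop = FALSE]
  }
  n <- ncol(X)
  L <- length(model$params$conv)
  means <- NULL; vars <- NULL; total <- 0
  for (from in seq(1, n, by = batch_size)) {
    to <- min(n, from + batch_size - 1)
    st <- .cnn_bn_stats_cpp(model$params, unclass(model$config),
                            X[, from:to, drop = FALSE])
    w <- to - from + 1
    if (is.null(means)) {
      means <- lapply(st$mean, `*`, w)
      vars <- lapply(st$var, `*`, w)
    } else {
      for (l in seq_len(L)) {
        means[[l]] <- means[[l]] + st$mean[[l]] * w
        vars[[l]] <- vars[[l]] + st$var[[l]] * w
      }
    }
    total <- total + w
  }
  for (l in seq_len(L)) {
    model$params$conv[[l]]$rmean <- means[[l]] / total
    model$params$conv[[l]]$rvar <- vars[[l]] / total
  }
  model
}

labels_onehot <- function(segments, n_out) {
  y <- vapply(segments, function(s) as.integer(s$label == "abnormal"), integer(1))
  if (n_out == 2) rbind(normal = 1 - y, abnormal = y)
  else matrix(y, nrow = 1, dimnames = list("abnormal", NULL))
}

#' Train the CNN with Adam on cross-entropy
#'
#' Runs `config$epochs` of mini-batch Adam, recording per-epoch training
#' loss/accuracy (averaged over the training batches, i.e. in training mode)
#' and validation loss/accuracy (inference mode) in `history`. Fully
#' reproducible from `config$seed` and the data order. With early stopping
#' enabled the returned model carries the weights of the best-validation-loss
#' epoch, otherwise of the final epoch.
#'
#' @param model An untrained or trained `pcg_cnn`.
#' @param train_set,val_set Non-empty [pcg_dataset]s whose segment length
#'   matches the model input length.
#' @param config A [train_config].
#' @return The trained `pcg_cnn` with a `history` data frame
#'   (`epoch, train_loss, train_acc, val_loss, val_acc`).
#' @export
train_model <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(model, "pcg_cnn"), inherits(config, "train_config"))
  pcg_assert(length(train_set$segments) > 0 && length(val_set$segments) > 0,
             "pcgnet_validation_error", "train and validation sets must be non-empty")
  cfg <- model$config
  X <- segments_matrix(train_set, cfg$input_len)
  shape <- model_shape(cfg)
  Y <- labels_onehot(train_set$segments, shape$n_out)
  y_val <- vapply(val_set$segments, `[[`, character(1), "label")
  n <- ncol(X)

  params <- model$params
  adam <- list(m = NULL, v = NULL, t = 0)
  slots <- param_slots(params)
  adam$m <- lapply(slots, function(s) get_slot(params, s) * 0)
  adam$v <- adam$m

  history <- data.frame()
  best <- list(val_loss = Inf, params = params, epoch = 0L)
  stale <- 0L

  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (from in seq(1, n, by = config$batch_size)) {
        idx <- ord[from:min(n, from + config$batch_size - 1)]
        drop_seed <- sample.int(.Machine$integer.max, 1)
        step <- .cnn_train_batch_cpp(params, unclass(cfg),
                                     X[, idx, drop = FALSE],
                                     Y[, idx, drop = FALSE], drop_seed)
        if (!is.finite(step$loss))
          pcg_error("pcgnet_divergence_error",
                    sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        ep_loss <- ep_loss + step$loss * length(idx)
        pred_ab <- if (shape$n_out == 2) step$probs[2, ] > step$probs[1, ]
                   else step$probs[1, ] > 0.5
        truth_ab <- Y[nrow(Y), idx] == 1
        ep_correct <- ep_correct + sum(pred_ab == truth_ab)
        # Adam update
        if (config$learning_rate > 0) {
          adam$t <- adam$t + 1
          bc1 <- 1 - config$beta1^adam$t
          bc2 <- 1 - config$beta2^adam$t
          for (si in seq_along(slots)) {
            g <- get_slot(step$grads, slots[[si]])
            adam$m[[si]] <- config$beta1 * adam$m[[si]] + (1 - config$beta1) * g
            adam$v[[si]] <- config$beta2 * adam$v[[si]] + (1 - config$beta2) * g^2
            upd <- config$learning_rate * (adam$m[[si]] / bc1) /
              (sqrt(adam$v[[si]] / bc2) + config$eps)
            params <- set_slot(params, slots[[si]],
                               get_slot(params, slots[[si]]) - upd)
          }
          for (l in seq_along(params$conv)) {
            params$conv[[l]]$rmean <- step$rmean[[l]]
            params$conv[[l]]$rvar <- step$rvar[[l]]
          }
        }
      }
      model$params <- params
      model <- recalibrate_bn(model, X, config$batch_size)
      params <- model$params
      val_probs <- model_forward(model, val_set)
      val_loss <- cross_entropy(y_val, val_probs)
      val_acc <- mean(ifelse(prob_abnormal(val_probs) > 0.5,
                             "abnormal", "normal") == y_val)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
        val_loss = val_loss, val_acc = val_acc))
      if (val_loss < best$val_loss) {
        best <- list(val_loss = val_loss, params = params, epoch = epoch)
        stale <- 0L
      } else stale <- stale + 1L
      if (!is.null(config$early_stop_patience) &&
          stale >= config$early_stop_patience) break
    }
  })
  if (!is.null(config$early_stop_patience)) model$params <- best$params
  else model$params <- params
  model$history <- history
  model$trained <- TRUE
  model$train_config <- config
  model
}
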