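test_that("cross-entropy matches its closed forms", {
  expect_lt(cross_entropy(1, 1 - 1e-7), 1e-6) # ~0 for a perfect prediction
  expect_equal(cross_entropy(1, 0.5), log(2))
  expect_equal(cross_entropy(c(1, 0), c(0.9, 0.2)),
               (-log(0.9) - log(0.8)) / 2)
  # extreme predictions are clipped, not infinite
  expect_true(is.finite(cross_entropy(c(1, 0), c(0, 1))))
  expect_error(cross_entropy(c(1, 0), 0.5), class = "pcgnet_validation_error")
  # label and matrix forms agree
  expect_equal(cross_entropy(c("abnormal", "normal"), c(0.9, 0.2)),
               cross_entropy(c(1, 0), c(0.9, 0.2)))
})

test_that("confusion counts with abnormal as the positive class", {
  truth <- rep(c("normal", "abnormal"), each = 5)
  cm <- confusion(truth, truth)
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]),
               c(tp = 5, tn = 5, fp = 0, fn = 0))
  cm2 <- confusion(c(rep("normal", 3), rep("abnormal", 2)),
                   rep("abnormal", 5))
  expect_equal(unlist(cm2[c("tp", "fp", "tn", "fn")]),
               c(tp = 2, fp = 3, tn = 0, fn = 0))
  expect_error(confusion("normal", "noisy"), class = "pcgnet_validation_error")
  expect_error(confusion(c("normal", "normal"), "normal"),
               class = "pcgnet_validation_error")
})

test_that("published confusion cells are internally consistent", {
  val <- confusion_from_counts(tp = 976, tn = 904, fp = 12, fn = 50)
  expect_equal(val$tp + val$tn + val$fp + val$fn, 1942)
  mv <- compute_metrics(val)
  expect_equal(mv$accuracy, (976 + 904) / 1942, tolerance = 1e-12)
  expect_equal(mv$accuracy, 0.9681, tolerance = 1e-4)
  expect_equal(mv$recall, 976 / 1026, tolerance = 1e-12)
  expect_equal(mv$recall, 0.9513, tolerance = 1e-4)
  expect_equal(mv$specificity, 904 / 916, tolerance = 1e-12)
  expect_equal(mv$specificity, 0.9869, tolerance = 1e-4)

  tst <- confusion_from_counts(tp = 1112, tn = 1069, fp = 28, fn = 76)
  expect_equal(tst$tp + tst$tn + tst$fp + tst$fn, 2285)
  mt <- compute_metrics(tst)
  expect_equal(mt$accuracy, 2181 / 2285, tolerance = 1e-12)
  expect_equal(mt$accuracy, 0.9545, tolerance = 1e-4)
})

test_that("metric identities hold on arbitrary confusion matrices", {
  withr::with_seed(8, {
    for (i in 1:20) {
      cm <- confusion_from_counts(tp = sample(0:50, 1), tn = sample(0:50, 1),
                                  fp = sample(0:50, 1), fn = sample(0:50, 1))
      total <- cm$tp + cm$tn + cm$fp + cm$fn
      if (total == 0) next
      m <- compute_metrics(cm)
      expect_equal(m$accuracy, (cm$tp + cm$tn) / total)
      if (!is.na(m$f1))
        expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
    }
  })
  perfect <- compute_metrics(confusion_from_counts(50, 50, 0, 0))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "f1", "specificity")]) == 1))
  # zero denominators are reported as undefined, never silently zero
  m0 <- compute_metrics(confusion_from_counts(tp = 0, tn = 10, fp = 0, fn = 5))
  expect_true(is.na(m0$precision))
  expect_true("precision" %in% m0$undefined)
  expect_error(compute_metrics(confusion_from_counts(0, 0, 0, 0)),
               class = "pcgnet_validation_error")
})

test_that("ROC/AUC handles the canonical cases", {
  sep <- roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(sep$auc, 1)
  tie <- roc_auc(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(tie$auc, 0.5)
  ex <- roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2))
  expect_equal(ex$auc, 0.75)
  # curve contract
  expect_equal(c(ex$fpr[1], ex$tpr[1]), c(0, 0))
  expect_equal(c(ex$fpr[length(ex$fpr)], ex$tpr[length(ex$tpr)]), c(1, 1))
  expect_true(all(diff(ex$fpr) >= 0) && all(diff(ex$tpr) >= 0))
  expect_true(all(diff(ex$thresholds) < 0))
  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), class = "pcgnet_validation_error")
})

test_that("trapezoidal AUC equals the Mann-Whitney pair statistic", {
  pair_auc <- function(y, s) { # brute force over all positive-negative pairs
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  withr::with_seed(123, {
    for (i in 1:50) {
      n <- sample(5:40, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      s <- round(stats::runif(n), sample(c(1, 2, 8), 1)) # induces ties
      expect_equal(roc_auc(y, s)$auc, pair_auc(y, s), tolerance = 1e-9)
    }
  })
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(77, {
    y <- sample(0:1, 60, replace = TRUE)
    y[1:2] <- 0:1
    s <- stats::runif(60)
  })
  ours <- roc_auc(y, s)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("a zero learning rate leaves trainable parameters untouched", {
  ds <- make_dataset(8, 8, len = 64)
  m <- build_model(tiny_model_config())
  before <- m$params
  out <- train_model(m, ds, ds, train_config(learning_rate = 0, epochs = 3,
                                             batch_size = 4, seed = 1))
  trainable <- function(p) list(
    conv = lapply(p$conv, function(l) l[c("W", "b", "gamma", "beta")]),
    dense = p$dense, head = p$head)
  expect_identical(trainable(out$params), trainable(before))
  expect_equal(nrow(out$history), 3)
})

test_that("the network can overfit a two-segment toy problem", {
  t_axis <- seq(0, 63) / 2000
  seg_n <- pcg_segment(sin(2 * pi * 125 * t_axis), fs = 2000, label = "normal",
                       source_id = "n")
  seg_a <- pcg_segment(sin(2 * pi * 500 * t_axis), fs = 2000,
                       label = "abnormal", source_id = "a")
  ds <- pcg_dataset(list(seg_n, seg_a))
  m <- build_model(tiny_model_config(dropout = FALSE, seed = 2))
  out <- train_model(m, ds, ds, train_config(epochs = 200, batch_size = 2,
                                             seed = 3))
  expect_lt(utils::tail(out$history$train_loss, 1), 0.05)
})

test_that("training is reproducible from seed and data order", {
  ds <- make_dataset(10, 10, len = 64)
  cfgm <- tiny_model_config(seed = 4)
  cfgt <- train_config(epochs = 3, batch_size = 8, seed = 21)
  h1 <- train_model(build_model(cfgm), ds, ds, cfgt)$history
  h2 <- train_model(build_model(cfgm), ds, ds, cfgt)$history
  expect_identical(h1, h2)
  h3 <- train_model(build_model(cfgm), ds, ds,
                    train_config(epochs = 3, batch_size = 8, seed = 22))$history
  expect_false(identical(h1$train_loss, h3$train_loss))
})

test_that("early stopping returns the best-validation weights", {
  ds <- make_dataset(12, 12, len = 64, seed = 2)
  val <- make_dataset(6, 6, len = 64, seed = 3)
  m <- build_model(tiny_model_config(seed = 8))
  out <- train_model(m, ds, val,
                     train_config(epochs = 8, batch_size = 8, seed = 5,
                                  early_stop_patience = 2))
  expect_lte(nrow(out$history), 8)
  best_epoch <- which.min(out$history$val_loss)
  expect_lte(nrow(out$history), best_epoch + 2)
})

test_that("model evaluation assembles a coherent report", {
  ds <- make_dataset(10, 10, len = 64, seed = 6)
  m <- build_model(tiny_model_config(seed = 11))
  path <- withr::local_tempfile(fileext = ".json")
  rep <- evaluate_model(m, ds, path = path)
  expect_equal(rep$n, 20)
  expect_equal(rep$confusion$tp + rep$confusion$tn +
                 rep$confusion$fp + rep$confusion$fn, 20)
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  parsed <- jsonlite::read_json(path)
  expect_named(parsed, c("n", "confusion", "metrics", "auc", "roc"))
})
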