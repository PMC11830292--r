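# Labeled segment collections and train/validation/test partitioning.

#' Assemble segments into a labeled dataset
#'
#' All segments must share one length and one sampling rate (the model-input
#' contract).
#'
#' @param segments List of [pcg_segment] objects (may be empty).
#' @return A `pcg_dataset` with fields `segments`, `n_normal`, `n_abnormal`.
#' @export
pcg_dataset <- function(segments = list()) {
  if (length(segments) > 0) {
    pcg_assert(all(vapply(segments, inherits, logical(1), "pcg_segment")),
               "pcgnet_validation_error", "all elements must be pcg_segment")
    lens <- vapply(segments, function(s) length(s$samples), integer(1))
    fss <- vapply(segments, function(s) s$fs, numeric(1))
    pcg_assert(length(unique(lens)) == 1, "pcgnet_validation_error",
               sprintf("segments must share one length, found: %s",
                       paste(unique(lens), collapse = ", ")))
    pcg_assert(length(unique(fss)) == 1, "pcgnet_validation_error",
               "segments must share one sampling rate")
  }
  labels <- vapply(segments, function(s) s$label, character(1))
  structure(list(segments = segments,
                 n_normal = sum(labels == "normal"),
                 n_abnormal = sum(labels == "abnormal")),
            class = "pcg_dataset")
}

#' Per-class segment tallies
#' @param dataset A [pcg_dataset].
#' @return Named integer vector `c(normal = , abnormal = )`; sums to the
#'   total segment count.
#' @export
class_counts <- function(dataset) {
  stopifnot(inherits(dataset, "pcg_dataset"))
  c(normal = dataset$n_normal, abnormal = dataset$n_abnormal)
}

#' @export
print.pcg_dataset <- function(x, ...) {
  cat(sprintf("<pcg_dataset> %d segments (%d normal, %d abnormal)\n",
              length(x$segments), x$n_normal, x$n_abnormal))
  invisible(x)
}

#' Sequential train/validation/test sizes
#'
#' The test size is rounded first, then the validation size is rounded from
#' the remainder: `n_test = round(test_frac * N)`;
#' `n_val = round(val_frac * (N - n_test))`; the rest trains. This sequential
#' rule is the default because it is the only rounding under which a nominal
#' 70/15/15 split of 15,231 segments gives 11,004 / 1,942 / 2,285; naive
#' simultaneous rounding (`"simultaneous"`) gives 2,285 / 2,285 and a smaller
#' training set.
#'
#' @param n Total segment count.
#' @param test_frac,val_frac Fractions in (0, 1) with sum below 1.
#' @param method `"sequential"` (default) or `"simultaneous"`.
#' @return Named vector `c(train = , val = , test = )` summing to `n`.
#' @export
split_sizes <- function(n, test_frac = 0.15, val_frac = 0.15,
                        method = c("sequential", "simultaneous")) {
  method <- match.arg(method)
  pcg_assert(test_frac + val_frac < 1 && test_frac > 0 && val_frac > 0,
             "pcgnet_validation_error", "need 0 < test_frac + val_frac < 1")
  if (method == "sequential") {
    n_test <- round(test_frac * n)
    n_val <- round(val_frac * (n - n_test))
  } else {
    n_test <- round(test_frac * n)
    n_val <- round(val_frac * n)
  }
  c(train = as.integer(n - n_test - n_val), val = as.integer(n_val),
    test = as.integer(n_test))
}

# Apportion `total` across classes proportionally to `weights`, by largest
# remainder, so per-part class ratios track the global ratio within one
# segment.
apportion <- function(total, weights) {
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a dataset into train/validation/test parts
#'
#' Stratified by class (per-part class ratios match the whole within one
#' segment) and grouped by `source_id` (all segments of one recording land in
#' one part, preventing leakage across the split). When recordings contribute
#' multiple segments, the grouped constraint can force per-part sizes to
#' deviate from the exact sequential-rounding targets by up to one group.
#'
#' @param dataset A [pcg_dataset] with at least 3 segments.
#' @param test_frac,val_frac Partition fractions (defaults 0.15 / 0.15,
#'   i.e. a nominal 70/15/15 split).
#' @param seed Integer seed for the shuffle; recorded in the result.
#' @param method Rounding rule, see [split_sizes()].
#' @return A `pcg_split` with fields `train`, `val`, `test` (each a
#'   [pcg_dataset]), `seed` and `sizes`.
#' @export
split_dataset <- function(dataset, test_frac = 0.15, val_frac = 0.15,
                          seed = 1L,
                          method = c("sequential", "simultaneous")) {
  stopifnot(inherits(dataset, "pcg_dataset"))
  method <- match.arg(method)
  N <- length(dataset$segments)
  pcg_assert(N >= 3, "pcgnet_validation_error",
             sprintf("dataset too small to split: %d segments", N))
  sizes <- split_sizes(N, test_frac, val_frac, method)
  cc <- class_counts(dataset)
  classes <- c("normal", "abnormal")
  test_c <- apportion(sizes["test"], cc)
  val_c <- apportion(sizes["val"], pmax(cc - test_c, 0))
  assign_part <- character(N)
  labels <- vapply(dataset$segments, function(s) s$label, character(1))
  sources <- vapply(dataset$segments, function(s) s$source_id, character(1))
  with_local_seed(seed, {
    for (ci in seq_along(classes)) {
      idx <- which(labels == classes[ci])
      groups <- split(idx, sources[idx])
      groups <- groups[sample(length(groups))]
      got_test <- 0L; got_val <- 0L
      for (g in groups) {
        if (got_test < test_c[ci] &&
            abs(got_test + length(g) - test_c[ci]) <= abs(got_test - test_c[ci])) {
          assign_part[g] <- "test"; got_test <- got_test + length(g)
        } else if (got_val < val_c[ci] &&
                   abs(got_val + length(g) - val_c[ci]) <= abs(got_val - val_c[ci])) {
          assign_part[g] <- "val"; got_val <- got_val + length(g)
        } else {
          assign_part[g] <- "train"
        }
      }
    }
  })
  part <- function(p) pcg_dataset(dataset$segments[assign_part == p])
  structure(list(train = part("train"), val = part("val"), test = part("test"),
                 seed = as.integer(seed), sizes = sizes, method = method),
            class = "pcg_split")
}

#' @export
print.pcg_split <- function(x, ...) {
  cat(sprintf("<pcg_split> train %d / val %d / test %d (seed %d, %s rounding)\n",
              length(x$train$segments), length(x$val$segments),
              length(x$test$segments), x$seed, x$method))
  invisible(x)
}

#' Read a `path,label` manifest
#' @param path CSV file with columns `path` and `label`
#'   (`normal`/`abnormal`).
#' @return data.frame with validated columns.
#' @export
read_manifest <- function(path) {
  pcg_assert(file.exists(path), "pcgnet_io_error",
             sprintf("manifest not found: %s", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  pcg_assert(all(c("path", "label") %in% names(m)), "pcgnet_format_error",
             "manifest must have columns 'path' and 'label'")
  bad <- setdiff(unique(m$label), c("normal", "abnormal"))
  pcg_assert(length(bad) == 0, "pcgnet_format_error",
             sprintf("unknown labels in manifest: %s", paste(bad, collapse = ", ")))
  m
}

#' Write a split as a manifest with a `split` column
#' @param split A `pcg_split`.
#' @param path Output CSV path.
#' @return `path`, invisibly. One row per segment
#'   (`source_id,start_s,label,split`).
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "pcg_split"))
  rows <- do.call(rbind, lapply(c("train", "val", "test"), function(p) {
    segs <- split[[p]]$segments
    if (length(segs) == 0) return(NULL)
    data.frame(source_id = vapply(segs, `[[`, character(1), "source_id"),
               start_s = vapply(segs, `[[`, numeric(1), "start_s"),
               label = vapply(segs, `[[`, character(1), "label"),
               split = p, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
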