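test_that("sequential rounding reproduces the published partition sizes", {
  expect_equal(split_sizes(15231, 0.15, 0.15),
               c(train = 11004, val = 1942, test = 2285))
  expect_equal(split_sizes(100, 0.15, 0.15),
               c(train = 72, val = 13, test = 15))
})

test_that("the partition property holds for every dataset size", {
  for (n in 3:2000) {
    sz <- split_sizes(n, 0.15, 0.15)
    expect_identical(sum(sz), n)
    expect_true(all(sz >= 0))
  }
  for (n in c(10L, 57L, 123L, 999L)) {
    expect_identical(sum(split_sizes(n, 0.2, 0.1)), n)
    expect_identical(sum(split_sizes(n, 0.15, 0.15, "simultaneous")), n)
  }
  expect_error(split_sizes(100, 0.6, 0.5), class = "pcgnet_validation_error")
})

test_that("splitting partitions the dataset with stratified class ratios", {
  ds <- make_dataset(120, 80, len = 8)
  sp <- split_dataset(ds, 0.15, 0.15, seed = 5)
  sizes <- vapply(list(sp$train, sp$val, sp$test),
                  function(d) length(d$segments), integer(1))
  expect_equal(sizes, unname(split_sizes(200, 0.15, 0.15))[c(1, 2, 3)])
  # disjoint union by source id (sources are singletons here)
  ids <- lapply(list(sp$train, sp$val, sp$test), function(d)
    vapply(d$segments, `[[`, character(1), "source_id"))
  expect_length(unique(unlist(ids)), 200)
  expect_equal(sum(lengths(ids)), 200)
  # per-part abnormal fraction within one segment of the global 40 %
  for (d in list(sp$train, sp$val, sp$test)) {
    cc <- class_counts(d)
    expect_lte(abs(cc["abnormal"] - 0.4 * sum(cc)), 1)
  }
})

test_that("splitting is deterministic in its seed", {
  ds <- make_dataset(30, 30, len = 8)
  s1 <- split_dataset(ds, seed = 42)
  s2 <- split_dataset(ds, seed = 42)
  expect_identical(s1, s2)
  s3 <- split_dataset(ds, seed = 43)
  ids <- function(sp) vapply(sp$test$segments, `[[`, character(1), "source_id")
  expect_false(identical(ids(s1), ids(s3)))
  expect_equal(s1$seed, 42L)
})

test_that("recordings never straddle the split", {
  ds <- make_dataset(60, 60, len = 8, segs_per_source = 4)
  sp <- split_dataset(ds, seed = 2)
  part_of <- c(rep("train", length(sp$train$segments)),
               rep("val", length(sp$val$segments)),
               rep("test", length(sp$test$segments)))
  src <- unlist(lapply(list(sp$train, sp$val, sp$test), function(d)
    vapply(d$segments, `[[`, character(1), "source_id")))
  expect_true(all(vapply(split(part_of, src), function(p)
    length(unique(p)) == 1, logical(1))))
  expect_equal(length(src), 120)
})

test_that("degenerate split inputs are rejected", {
  expect_error(split_dataset(make_dataset(1, 1, len = 8)),
               class = "pcgnet_validation_error")
})

test_that("class counts tally exactly", {
  expect_equal(unname(class_counts(pcg_dataset())), c(0, 0))
  ds <- make_dataset(7, 4, len = 8)
  cc <- class_counts(ds)
  expect_equal(unname(cc), c(7, 4))
  expect_equal(sum(cc), length(ds$segments))
  bal <- balance_classes(make_dataset(5, 3, len = 256))
  expect_equal(unname(diff(class_counts(bal))), 0)
})

test_that("datasets enforce the shared-length contract", {
  a <- pcg_segment(rnorm(8), fs = 2000, label = "normal")
  b <- pcg_segment(rnorm(9), fs = 2000, label = "abnormal")
  expect_error(pcg_dataset(list(a, b)), class = "pcgnet_validation_error")
  c2 <- pcg_segment(rnorm(8), fs = 1000, label = "abnormal")
  expect_error(pcg_dataset(list(a, c2)), class = "pcgnet_validation_error")
})

test_that("manifests round-trip and validate labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(path = c("a.wav", "b.wav"),
                              label = c("normal", "abnormal")),
                   path, row.names = FALSE)
  m <- read_manifest(path)
  expect_equal(m$label, c("normal", "abnormal"))
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(path = "a.wav", label = "murmur"), bad,
                   row.names = FALSE)
  expect_error(read_manifest(bad), class = "pcgnet_format_error")
  # split manifest carries one row per segment with its partition
  sp <- split_dataset(make_dataset(10, 10, len = 8), seed = 1)
  out <- withr::local_tempfile(fileext = ".csv")
  write_split_manifest(sp, out)
  sm <- utils::read.csv(out)
  expect_equal(nrow(sm), 20)
  expect_setequal(unique(sm$split), c("train", "val", "test"))
})
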