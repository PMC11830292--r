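test_that("shape algebra follows the pooling schedule", {
  cfg16k <- model_config(input_len = 16000)
  expect_equal(model_shape(cfg16k)$time_steps, 250) # 16000 / 2^6
  expect_equal(model_shape(cfg16k)$flat_len, 4000)  # 250 x 16 filters
  cfg8k <- model_config(input_len = 8000)
  expect_equal(model_shape(cfg8k)$time_steps, 125)
  expect_error(model_config(input_len = 1000),
               regexp = "not divisible.*2\\^6 = 64",
               class = "pcgnet_validation_error")
  # time length after every block is input_len / pool^l
  cfg <- tiny_model_config(input_len = 64)
  expect_equal(64 / cfg$pool_size^cfg$n_blocks * cfg$conv_filters[2],
               model_shape(cfg)$flat_len)
})

test_that("softmax is stable, normalized, and shift-invariant", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(3, 3, 3)), rep(1 / 3, 3))
  expect_equal(softmax(log(c(1, 3))), c(0.25, 0.75))
  z <- c(-2, 0.5, 4)
  expect_equal(softmax(z), softmax(z + 123), tolerance = 1e-12)
  expect_equal(unname(rowSums(softmax(matrix(c(1000, -1000, 0, 0), 2)))),
               c(1, 1))
  expect_error(softmax(c(1, NA)), class = "pcgnet_validation_error")
})

test_that("forward output is a valid probability object for both heads", {
  segs <- make_dataset(20, 20, len = 64)$segments
  m2 <- build_model(tiny_model_config(head = "softmax2"))
  p2 <- model_forward(m2, segs)
  expect_equal(dim(p2), c(40, 2))
  expect_true(all(p2 > 0 & p2 < 1))
  expect_equal(unname(rowSums(p2)), rep(1, 40), tolerance = 1e-6)

  m1 <- build_model(tiny_model_config(head = "sigmoid1"))
  p1 <- model_forward(m1, segs)
  expect_equal(dim(p1), c(40, 1))
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("probability validity holds across many random inputs", {
  m <- build_model(tiny_model_config(seed = 99))
  segs <- make_dataset(500, 500, len = 64, seed = 4)$segments
  p <- model_forward(m, segs)
  expect_equal(unname(rowSums(p)), rep(1, 1000), tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
})

test_that("inference is deterministic and batching-invariant", {
  m <- build_model(tiny_model_config())
  segs <- make_dataset(5, 5, len = 64)$segments
  segs <- c(segs, segs[1]) # duplicated segment
  p1 <- model_forward(m, segs)
  p2 <- model_forward(m, segs)
  expect_equal(p1, p2, tolerance = 1e-7)
  expect_equal(p1[11, ], p1[1, ], tolerance = 1e-7)
  p3 <- model_forward(m, segs, batch_size = 3)
  expect_equal(p1, p3, tolerance = 1e-6)
})

test_that("segment length mismatches are named in the error", {
  m <- build_model(tiny_model_config(input_len = 64))
  bad <- pcg_segment(rnorm(32), fs = 2000, label = "normal")
  expect_error(model_forward(m, list(bad)), regexp = "expects 64.*got 32")
})

test_that("weight initialization is reproducible from the config seed", {
  m1 <- build_model(tiny_model_config(seed = 5))
  m2 <- build_model(tiny_model_config(seed = 5))
  m3 <- build_model(tiny_model_config(seed = 6))
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params$conv[[1]]$W, m3$params$conv[[1]]$W))
})

test_that("checkpoints round-trip through save/load", {
  m <- build_model(tiny_model_config())
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$config, m$config)
  expect_identical(m2$params, m$params)
  notchk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), notchk)
  expect_error(load_model(notchk), class = "pcgnet_format_error")
})
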