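labeled <- function(samples, fs = 2000)
  audio_signal(samples, fs = fs, source_id = "rec1", label = "abnormal")

test_that("an exact multiple of the window tiles losslessly", {
  s <- labeled(withr::with_seed(2, stats::rnorm(16000)))
  segs <- segment_signal(s, seg_seconds = 4, overlap_frac = 0)
  expect_length(segs, 2)
  expect_true(all(vapply(segs, function(g) length(g$samples), integer(1)) == 8000))
  expect_equal(unlist(lapply(segs, `[[`, "samples")), s$samples)
  expect_true(all(vapply(segs, `[[`, character(1), "label") == "abnormal"))
})

test_that("a trailing partial window is padded to full length", {
  s <- labeled(seq_len(20000)) # 10 s at 2000 Hz
  segs <- segment_signal(s, seg_seconds = 4, overlap_frac = 0)
  expect_length(segs, 3) # ceiling((10 - 4) / 4) + 1
  third <- segs[[3]]$samples
  expect_length(third, 8000)
  expect_equal(third[1:4000], s$samples[16001:20000])
  expect_equal(third[4001:8000], s$samples[16001:20000]) # wrap padding
  expect_equal(segs[[3]]$start_s, 8)
})

test_that("overlapping windows start at the hop grid", {
  s <- labeled(stats::rnorm(20000))
  segs <- segment_signal(s, seg_seconds = 4, overlap_frac = 0.5)
  expect_length(segs, 4)
  expect_equal(vapply(segs, `[[`, numeric(1), "start_s"), c(0, 2, 4, 6))
  expect_error(segment_signal(s, 4, overlap_frac = 1),
               class = "pcgnet_validation_error")
  expect_error(segment_signal(s, 4, overlap_frac = -0.1),
               class = "pcgnet_validation_error")
})

test_that("padding modes behave per definition", {
  expect_equal(pad_segment(c(1, 2, 3), 7, "wrap"), c(1, 2, 3, 1, 2, 3, 1))
  expect_equal(pad_segment(c(1, 2, 3), 5, "zero"), c(1, 2, 3, 0, 0))
  expect_equal(pad_segment(c(1, 2), 2, "wrap"), c(1, 2))
  expect_equal(pad_segment(c(1, 2), 2, "zero"), c(1, 2))
  expect_error(pad_segment(1:5, 3), class = "pcgnet_validation_error")
})

test_that("pitch shifting moves spectral content by the requested ratio", {
  seg <- segment_signal(labeled(sin(2 * pi * 100 * seq(0, 4, by = 1 / 2000))[1:8000]),
                        seg_seconds = 4)[[1]]
  sh <- pitch_shift(seg, 1.23)
  expect_length(sh$samples, 8000)
  expect_equal(sh$fs, seg$fs)
  expect_true(sh$augmented)
  expect_equal(sh$label, seg$label)
  expect_equal(fft_peak_hz(sh$samples, 2000), 123, tolerance = 2000 / 8000)
})

test_that("the default ratio maps the 650 Hz band edge to 800 Hz", {
  seg <- segment_signal(labeled(sin(2 * pi * 650 * seq(0, 4, by = 1 / 2000))[1:8000]),
                        seg_seconds = 4)[[1]]
  sh <- pitch_shift(seg, 800 / 650)
  expect_length(sh$samples, 8000)
  expect_equal(fft_peak_hz(sh$samples, 2000), 800, tolerance = 2000 / 8000)
})

test_that("pitch shift identity and aliasing guard", {
  seg <- segment_signal(labeled(stats::rnorm(8000)), seg_seconds = 4)[[1]]
  same <- pitch_shift(seg, 1)
  expect_lt(rms(same$samples - seg$samples), 1e-3 * rms(seg$samples))
  expect_error(pitch_shift(seg, 1.6), class = "pcgnet_validation_error")
  expect_error(pitch_shift(seg, -1), class = "pcgnet_validation_error")
})

test_that("class balancing augments the minority up to parity", {
  ds <- make_dataset(10, 10)
  expect_identical(balance_classes(ds), ds)

  ds2 <- make_dataset(10, 6, len = 256)
  bal <- balance_classes(ds2, seed = 3)
  expect_equal(unname(class_counts(bal)), c(10, 10))
  new_segs <- bal$segments[seq(17, 20)]
  expect_true(all(vapply(new_segs, `[[`, logical(1), "augmented")))
  expect_true(all(vapply(new_segs, `[[`, character(1), "label") == "abnormal"))
  # originals retained
  expect_identical(bal$segments[1:16], ds2$segments)

  expect_error(balance_classes(make_dataset(1, 0)),
               class = "pcgnet_validation_error")
})

test_that("balancing is reproducible from its seed", {
  ds <- make_dataset(8, 5, len = 256)
  b1 <- balance_classes(ds, seed = 11)
  b2 <- balance_classes(ds, seed = 11)
  expect_identical(b1, b2)
})
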