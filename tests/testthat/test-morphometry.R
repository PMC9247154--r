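test_that("median filter matches a brute-force oracle and has identity cases", {
  withr::with_seed(14, {
    arr <- array(runif(6 * 7 * 5, 0, 100), dim = c(6, 7, 5))
  })
  v <- volume(arr, 1)
  expect_identical(median_filter_volume(v, 0)$data, arr)       # radius 0
  const <- volume(array(42, dim = c(6, 6, 6)), 1)
  expect_true(all(median_filter_volume(const, 2)$data == 42))  # constant
  # brute-force reflect-boundary median with radius 1
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  d <- dim(arr)
  want <- array(0, dim = d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    nb <- numeric(0)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      nb <- c(nb, arr[reflect(z + dz, d[1]), reflect(y + dy, d[2]),
                      reflect(x + dx, d[3])])
    }
    want[z, y, x] <- median(nb)
  }
  expect_equal(median_filter_volume(v, 1)$data, want, tolerance = 1e-12)
  # an isolated impulse in a constant field is removed at radius 2
  imp <- array(10, dim = c(9, 9, 9)); imp[5, 5, 5] <- 1000
  out <- median_filter_volume(volume(imp, 1), 2)
  expect_true(all(out$data == 10))
})

test_that("threshold segmentation uses inclusive intervals and named presets", {
  arr <- array(rep(c(30000, 31000), each = 4), dim = c(2, 2, 2))
  v <- volume(arr, 1)
  expect_true(all(threshold_segment(v, c(0, 65535))))
  half <- threshold_segment(v, c(30375, 65535))
  expect_equal(mean(half), 0.5)
  expect_identical(attr(half, "threshold"), c(30375, 65535))
  presets <- bvtv_threshold_presets()
  expect_identical(presets[["next"]], c(30375, 65535))
  expect_identical(presets[["4dlab"]], c(53500, 65535))
  p4 <- threshold_segment(v, preset = "4dlab")
  expect_false(any(p4))
  expect_error(threshold_segment(v, c(40000, 30000)), "inverted")
  expect_error(threshold_segment(v, preset = "nope"), "preset")
})

test_that("bvtv is the bone fraction of the specimen mask", {
  m <- array(c(TRUE, FALSE), dim = c(4, 4, 4))
  expect_equal(bvtv(m, m)$bvtv, 1)
  none <- array(FALSE, dim = c(4, 4, 4))
  all_in <- array(TRUE, dim = c(4, 4, 4))
  expect_equal(bvtv(none, all_in)$bvtv, 0)
  expect_error(bvtv(m, none), "empty")
  expect_error(bvtv(m, array(TRUE, dim = c(2, 2, 2))), "shape")
})

test_that("the filter+threshold pipeline recovers the phantom bone fraction", {
  ph <- generate_volume(xray_plug_spec(0.3, n = 96, seed = 17))
  truth <- ph$phases$achieved_fraction[ph$phases$label == "bone"]
  res <- bvtv_pipeline(ph$volume)
  expect_lt(abs(res$bvtv - truth), 0.02)
  expect_identical(res$threshold, c(30375, 65535))
  expect_identical(res$filter_radius, 2L)
})

test_that("raising the lower threshold never increases BV/TV", {
  ph <- generate_volume(xray_plug_spec(0.25, n = 64, seed = 19))
  filt <- median_filter_volume(ph$volume, 2)
  sm <- !label_mask(ph, "background")
  lows <- seq(20000, 50000, by = 5000)
  vals <- sapply(lows, function(lo) {
    bvtv(threshold_segment(filt, c(lo, 65535)), sm)$bvtv
  })
  expect_true(all(diff(vals) <= 0))
})

test_that("the radius-2 median filter barely moves noiseless BV/TV", {
  ph <- generate_volume(xray_plug_spec(0.3, n = 96, noise_sigma = 0,
                                       seed = 23))
  sm <- !label_mask(ph, "background")
  b0 <- bvtv(threshold_segment(ph$volume, preset = "next"), sm)$bvtv
  b2 <- bvtv(threshold_segment(median_filter_volume(ph$volume, 2),
                               preset = "next"), sm)$bvtv
  expect_lt(abs(b2 - b0), 0.01)
})
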