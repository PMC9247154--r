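test_that("specimen mask recovers the phantom interior and rejects empty volumes", {
  ph <- generate_volume(plug_phantom_spec("rehydrated", n = 48, seed = 3))
  m <- specimen_mask(ph$volume)
  truth <- ph$labels != 1L
  recall <- sum(m & truth) / sum(truth)
  expect_gte(recall, 0.99)
  # all-background volume: segmentation failure
  flat <- volume(array(4000, dim = c(12, 12, 12)), 1)
  expect_error(specimen_mask(flat), "segmentation failure")
  # idempotence: masking a masked volume leaves the mask unchanged
  masked <- apply_mask(ph$volume, m)
  expect_identical(specimen_mask(masked), m)
})

test_that("phase histogram conserves counts with 250 bins by default", {
  ph <- generate_volume(plug_phantom_spec("dry", n = 32, seed = 2))
  m <- specimen_mask(ph$volume)
  h <- phase_histogram(ph$volume, m)
  expect_identical(h$n_bins, 250L)
  expect_identical(sum(h$counts), h$n_masked)
  expect_identical(h$n_masked + h$excluded_background, length(ph$volume$data))
  # fixed-range mode still conserves (out-of-range voxels land in end bins)
  hf <- phase_histogram(ph$volume, m, range = c(20000, 40000))
  expect_identical(sum(hf$counts), hf$n_masked)
  # two-value noiseless volume: exactly two occupied bins
  tp <- two_phase_volume(n = 8)
  h2 <- phase_histogram(tp$volume, array(TRUE, dim = c(8, 8, 8)))
  expect_identical(sum(h2$counts > 0), 2L)
  expect_error(phase_histogram(tp$volume, array(TRUE, dim = c(8, 8, 8)),
                               n_bins = 1), "n_bins")
  expect_error(phase_histogram(tp$volume, array(FALSE, dim = c(8, 8, 8))),
               "empty")
})

test_that("well-separated phases produce labelled peaks at the phase means", {
  # three-phase mixture with small noise: peaks must land on the right bins
  withr::with_seed(10, {
    vals <- c(rnorm(30000, 15000, 600), rnorm(40000, 33000, 600),
              rnorm(50000, 43000, 600))
    vol <- volume(array(sample(vals), dim = c(30, 40, 100)), 1)
  })
  h <- phase_histogram(vol, array(TRUE, dim = dim(vol$data)))
  pk <- detect_peaks(h)
  expect_true(all(pk$present))
  bw <- diff(h$bin_edges[1:2])
  expect_true(all(abs(pk$location - c(15000, 33000, 43000)) <= 1.5 * bw))
  # grey-ordering invariant: void < bone < marrow
  expect_true(all(diff(pk$location) > 0))
  expect_false(attr(pk, "any_merged"))
})

test_that("missing and merged peaks are reported as such", {
  mk_hist <- function(means, ns, sd = 600) {
    withr::with_seed(11, {
      vals <- unlist(mapply(function(m, n) rnorm(n, m, sd), means, ns,
                            SIMPLIFY = FALSE))
      vol <- volume(array(vals, dim = c(length(vals), 1, 1)), 1)
    })
    phase_histogram(vol, array(TRUE, dim = c(length(vals), 1, 1)))
  }
  # unimodal: one peak, the rest absent
  h1 <- mk_hist(25000, 50000)
  pk1 <- detect_peaks(h1, anchors = c(void = 15000, bone = 25000,
                                      marrow = 43000))
  expect_identical(pk1$present, c(FALSE, TRUE, FALSE))
  # no void phase: void peak absent
  h2 <- mk_hist(c(33000, 43000), c(40000, 50000))
  pk2 <- detect_peaks(h2, anchors = c(void = 15000, bone = 33000,
                                      marrow = 43000))
  expect_false(pk2$present[pk2$label == "void"])
  expect_true(all(pk2$present[pk2$label != "void"]))
  # bone and marrow within one noise-FWHM of each other: merged flag
  fwhm <- fwhm_from_sigma(600)
  h3 <- mk_hist(c(15000, 33000, 33000 + 0.8 * fwhm), c(20000, 40000, 50000))
  pk3 <- detect_peaks(h3, anchors = c(void = 15000, bone = 33000,
                                      marrow = 33000 + 0.8 * fwhm))
  expect_true(all(pk3$merged[pk3$label %in% c("bone", "marrow")]))
  expect_true(attr(pk3, "any_merged"))
  expect_false(pk3$merged[pk3$label == "void"])
})

test_that("separation score measures valley depth between peaks", {
  counts <- c(0, 100, 0, 0, 0, 100, 0)
  h <- structure(list(
    bin_edges = seq(0, 7), bin_centers = seq(0.5, 6.5), counts = counts,
    n_bins = 7L, n_masked = sum(counts), excluded_background = 0L
  ), class = "phase_histogram")
  expect_equal(separation_score(1.5, 5.5, h), 1)   # empty valley
  flat <- h; flat$counts <- c(0, 100, 100, 100, 100, 100, 0)
  expect_equal(separation_score(1.5, 5.5, flat), 0)  # no valley
  expect_true(is.na(separation_score(1.5, 1.5, h)))  # coincident: flagged
  # deeper valleys score higher as the means separate (noiseless sweep)
  scores <- sapply(c(2000, 4000, 8000), function(delta) {
    x <- seq(10000, 30000, length.out = 250)
    cts <- round(3e4 * (dnorm(x, 18000, 900) + dnorm(x, 18000 + delta, 900)))
    hh <- structure(list(
      bin_edges = seq(10000, 30000, length.out = 251), bin_centers = x,
      counts = cts, n_bins = 250L, n_masked = sum(cts),
      excluded_background = 0L
    ), class = "phase_histogram")
    separation_score(18000, 18000 + delta, hh)
  })
  expect_true(all(diff(scores) > 0))
})
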