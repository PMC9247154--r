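test_that("extract_profile averages transversely and respects bounds", {
  # constant volume -> constant profile
  flat <- volume(array(500, dim = c(8, 16, 16)), voxel_size = 2)
  p <- extract_profile(flat, 4, c(8, 2, 8, 15), averaging_width = 3)
  expect_true(all(abs(p$values - 500) < 1e-9))
  expect_equal(p$abscissa[2] - p$abscissa[1], 2)  # physical units
  # two-phase phantom: profile attains both plateau values
  ph <- two_phase_volume(n = 16)
  p2 <- extract_profile(ph$volume, 8, c(8, 2, 8, 15), units = "px")
  expect_equal(min(p2$values), 1000)
  expect_equal(max(p2$values), 3000)
  # wider transverse averaging lowers the plateau variance
  noisy <- two_phase_volume(n = 24, noise = 500, seed = 4)
  v1 <- var(extract_profile(noisy$volume, 12, c(12, 2, 12, 23), 1, "px")$values[1:8])
  v11 <- var(extract_profile(noisy$volume, 12, c(12, 2, 12, 23), 11, "px")$values[1:8])
  expect_lt(v11, v1)
  expect_error(extract_profile(ph$volume, 8, c(8, 2, 8, 40)), "bounds")
  expect_error(extract_profile(ph$volume, 8, c(8, 2, 8, 15), 4), "odd")
})

test_that("condition_profile preserves polynomials and suppresses noise", {
  x <- seq(0, 10, by = 0.5)
  y <- 2 + 3 * x - 0.5 * x^2 + 0.01 * x^3
  p <- line_profile(x, y)
  same <- condition_profile(p, upsample = 1)
  expect_equal(same$abscissa, x)          # upsample 1: abscissa unchanged
  expect_equal(same$values, y, tolerance = 1e-10)
  up <- condition_profile(p, upsample = 4)
  expect_length(up$values, (length(x) - 1) * 4 + 1)
  # residual vs the clean generator output shrinks after conditioning
  clean <- generate_edge_profile(0, 2, c(0, 1), n_points = 81)
  noisy <- generate_edge_profile(0, 2, c(0, 1), n_points = 81,
                                 noise_sigma = 0.05, seed = 11)
  cond <- condition_profile(noisy, upsample = 1)
  expect_lt(sd(cond$values - clean$values), sd(noisy$values - clean$values))
  expect_error(condition_profile(p, savgol_span = 8), "odd")
  expect_error(condition_profile(p, savgol_span = 3), "order")
  expect_error(condition_profile(line_profile(1:5, 1:5)), "length")
})

test_that("fit_edge recovers the generating parameters of a noiseless edge", {
  f <- fit_edge(generate_edge_profile(0, 2, c(0, 1)))
  expect_true(f$converged)
  expect_equal(f$sigma, 2, tolerance = 1e-6)
  expect_equal(f$fwhm, 4.7096, tolerance = 1e-4)
  expect_lt(f$nrmse, 1e-8)
  expect_true(f$mu >= f$window[1] && f$mu <= f$window[2])
  # explicit fit window
  fw <- fit_edge(generate_edge_profile(0, 1, c(0, 1), half_width = 12,
                                       n_points = 97), window = c(-6, 6))
  expect_equal(fw$sigma, 1, tolerance = 1e-6)
  expect_error(fit_edge(line_profile(1:4, 1:4)), "6 samples")
})

test_that("the FWHM/sigma ratio is the Gaussian constant for every converged fit", {
  for (s in c(0.5, 1, 2, 4)) {
    f <- fit_edge(generate_edge_profile(1, s, c(100, 900), half_width = 20,
                                        n_points = 161))
    expect_equal(f$fwhm / f$sigma, 2.3548, tolerance = 5e-5)
  }
})

test_that("falling edges fit like mirrored rising edges", {
  rise <- fit_edge(generate_edge_profile(0.4, 1.5, c(0, 1), n_points = 121))
  fall <- fit_edge(generate_edge_profile(0.4, 1.5, c(1, 0), n_points = 121))
  expect_equal(fall$sigma, rise$sigma, tolerance = 1e-8)
  expect_identical(fall$polarity, "falling")
  expect_identical(rise$polarity, "rising")
})

test_that("nrmse normalizes by the observed range", {
  expect_equal(nrmse(c(0, 1, 0.5), c(0, 1, 0.5)), 0)
  expect_equal(nrmse(c(0, 1), c(0.5, 0.5)), 0.5)
  obs <- c(0, 0.2, 1); fit <- c(0.1, 0.3, 0.8)
  expect_equal(nrmse(obs * 10, fit * 10), nrmse(obs, fit))  # scale invariance
  expect_error(nrmse(c(1, 1), c(1, 2)), "range")
  expect_error(nrmse(1:3, 1:4), "length")
})

test_that("gradient-based window proposal flags the edge location", {
  p <- generate_edge_profile(0, 1, c(0, 1), half_width = 10, n_points = 81)
  w <- propose_edge_windows(p)
  expect_equal(nrow(w), 1)
  expect_lt(abs(w$center), 0.5)
})
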