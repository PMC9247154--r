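test_that("phase painting partitions the volume and respects declaration order", {
  ph <- two_phase_volume(n = 12, lo = 1000, hi = 3000)
  # no blur, no noise: exactly the two declared grey values
  expect_setequal(unique(as.vector(ph$volume$data)), c(1000, 3000))
  # partition: label counts sum to the voxel count
  expect_identical(sum(table(ph$labels)), length(ph$labels))
  # later phase wins on its half
  expect_true(all(ph$volume$data[, , 12] == 3000))
  expect_true(all(ph$volume$data[, , 1] == 1000))
})

test_that("unclaimed voxels are a configuration error", {
  spec <- phantom_spec(
    shape = c(8, 8, 8), voxel_size = 1,
    phases = list(phantom_phase("blob", geom_sphere(c(4, 4, 4), 2), 100))
  )
  expect_error(generate_volume(spec), "no phase")
})

test_that("rod lattice hits its target fraction and records the achieved value", {
  spec <- xray_plug_spec(target_bvtv = 0.3, n = 96, noise_sigma = 0, seed = 21)
  ph <- generate_volume(spec)
  ach <- ph$phases$achieved_fraction[ph$phases$label == "bone"]
  expect_true(abs(ach - 0.3) < 0.02)
  # the recorded value is exact with respect to the label map
  region <- ph$labels != 1L
  bone <- ph$labels == 3L
  expect_equal(sum(bone) / sum(region), ach, tolerance = 1e-12)
})

test_that("identical spec and seed give bit-identical output from every generator", {
  sp <- plug_phantom_spec("dry", n = 24, seed = 42)
  expect_identical(generate_volume(sp)$volume$data,
                   generate_volume(sp)$volume$data)
  p1 <- generate_edge_profile(0, 1, noise_sigma = 0.05, seed = 7)
  p2 <- generate_edge_profile(0, 1, noise_sigma = 0.05, seed = 7)
  expect_identical(p1$values, p2$values)
  cs <- compression_spec(0.25, noise_sigma = 0.1, seed = 5)
  expect_identical(generate_compression_curve(cs)$record,
                   generate_compression_curve(cs)$record)
  ws <- weight_series_spec(noise_sigma = 0.01, seed = 9)
  expect_identical(generate_weight_series(ws), generate_weight_series(ws))
})

test_that("Gaussian blur preserves the volume mean under mirror boundaries", {
  sp <- edge_phantom_spec(n = 24, blur_sigma_um = 15, noise_sigma = 0)
  ph <- generate_volume(sp)
  unblurred <- two_phase_volume(n = 24, lo = 10000, hi = 40000)
  # boundary-handling tolerance: 0.1 % of the mean
  expect_equal(mean(ph$volume$data), mean(unblurred$volume$data),
               tolerance = 1e-3)
})

test_that("edge-profile generator samples the Gaussian CDF exactly", {
  p <- generate_edge_profile(0, 2, levels = c(0, 1), n_points = 9,
                             half_width = 4)
  # abscissa hits mu and mu + sigma on this grid
  expect_equal(p$values[p$abscissa == 0], 0.5)
  expect_equal(p$values[p$abscissa == 2], pnorm(1), tolerance = 1e-12)
  wide <- generate_edge_profile(0, 2, levels = c(5, 9), half_width = 16)
  expect_equal(wide$values[1], 5, tolerance = 1e-8)   # low-level limit
  expect_error(generate_edge_profile(0, -1), "sigma")
  expect_error(generate_edge_profile(0, 1, n_points = 4), "n_points")
})

test_that("compression generator matches its configured mechanics", {
  cc <- generate_compression_curve(compression_spec(0.3))
  ss <- normalize_curve(cc$record, cc$geometry)
  # finite-difference slope oracle on the noiseless ramp
  slopes <- diff(ss$stress) / diff(ss$strain)
  expect_equal(max(slopes), cc$truth$modulus_mpa, tolerance = 1e-6)
  # monotone curve when the post-peak drop is zero: no interior peak
  cc0 <- generate_compression_curve(compression_spec(0.3, post_peak_drop = 0))
  ss0 <- normalize_curve(cc0$record, cc0$geometry)
  expect_false(find_failure(ss0)$clear_peak)
  expect_true(all(diff(ss0$stress) > -1e-9))
  # strength increases with bone volume fraction
  pk <- function(f) max(generate_compression_curve(compression_spec(f))$record$force_N)
  expect_lt(pk(0.15), pk(0.35))
  expect_error(compression_spec(0.3, diameter_mm = 0), "positive")
})

test_that("weight-series generator follows exponential-approach kinetics", {
  ws <- weight_series_spec(initial_weight = 10, noise_sigma = 0)
  log <- generate_weight_series(ws)
  expect_equal(log$weight_g[log$stage == "initial"], 10)
  # 97 % of a 10 % loss by 3 h
  wd <- log$weight_g[log$stage == "post-dry"]
  expect_equal(percent_change(10, wd), -9.7, tolerance = 1e-6)
  # drying asymptote
  long <- weight_series_spec(initial_weight = 10, drying_duration = 100,
                             sampling_times = seq(0, 100, 10), noise_sigma = 0)
  wl <- generate_weight_series(long)
  expect_equal(min(wl$weight_g), 9, tolerance = 1e-4)
  # drying non-increasing, rehydration non-decreasing in expectation
  expect_true(all(diff(wl$weight_g[wl$stage %in% c("initial", "drying", "post-dry")]) <= 0))
  reh <- log$weight_g[log$stage == "rehydration"]
  expect_true(all(diff(reh) >= 0))
  expect_error(weight_series_spec(sampling_times = c(-1, 3)), "times")
})
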