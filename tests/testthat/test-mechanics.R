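test_that("normalization applies geometry and the preload convention", {
  # 2827.4 N over a 6 mm circle is ~100 MPa; 0.1 mm over 10 mm is 1 % strain
  rec <- tibble::tibble(
    force_N = c(5, 15, 2827.4),
    displacement_mm = c(0, 0.05, 0.15)
  )
  ss <- normalize_curve(rec)
  expect_equal(max(ss$stress), 100, tolerance = 1e-4)
  expect_equal(min(ss$strain), 0)
  expect_equal(max(ss$strain), 0.01, tolerance = 1e-9)
  # crossing interpolated between samples: zero strain at F = 15 N exactly
  rec2 <- tibble::tibble(force_N = c(0, 30), displacement_mm = c(0, 1))
  ss2 <- normalize_curve(rec2)
  expect_equal(ss2$stress[1], 15 / (pi * 9))
  expect_equal(ss2$strain[2], (1 - 0.5) / 10)
  expect_error(normalize_curve(tibble::tibble(force_N = c(1, 5),
                                              displacement_mm = c(0, 1))),
               "preload not reached")
  expect_error(normalize_curve(rec, geometry = list(diameter_mm = -1,
                                                    height_mm = 10)),
               "positive")
})

test_that("failure is the first clear peak, not the global maximum", {
  mono <- as_ss(seq(0, 0.05, 0.001), seq(0, 80, length.out = 51))
  expect_false(find_failure(mono)$clear_peak)
  tri <- triangle_ss(eps_f = 0.04, s_f = 80)
  fl <- find_failure(tri, smooth = 1)
  expect_true(fl$clear_peak)
  expect_equal(fl$failure_strain, 0.04)
  expect_equal(fl$peak_stress, 80)
  # two clear peaks, the first smaller: the first is returned
  eps <- seq(0, 0.1, 5e-4)
  s <- 60 * exp(-((eps - 0.03) / 0.008)^2) + 90 * exp(-((eps - 0.07) / 0.008)^2)
  two <- as_ss(eps, s)
  fl2 <- find_failure(two, smooth = 1)
  expect_equal(fl2$failure_strain, 0.03, tolerance = 0.01)
  expect_lt(fl2$peak_stress, 70)
})

test_that("modulus comes from the steepest sliding window, skipping the toe", {
  line <- as_ss(seq(0, 0.02, 1e-4), 1500 * seq(0, 0.02, 1e-4))
  m <- modulus(line, end_strain = 0.02)
  expect_equal(m$modulus, 1500, tolerance = 1e-9)
  # concave-up toe then a true linear region of slope 2000
  eps <- seq(0, 0.03, 1e-4)
  toe_end <- 0.01
  stress <- ifelse(eps < toe_end, 2000 * eps^2 / (2 * toe_end),
                   2000 * (eps - toe_end / 2))
  toe <- as_ss(eps, stress)
  mt <- modulus(toe, end_strain = 0.03)
  expect_equal(mt$modulus, 2000, tolerance = 1e-6)
  expect_gte(mt$window[1], toe_end - 1e-9)
  expect_error(modulus(as_ss(seq(0, 0.002, 1e-4), seq(0, 1, length.out = 21)),
                       end_strain = 0.002, window_strain_width = 0.005),
               "insufficient")
})

test_that("modulus recovery from noisy generator curves stays within 5 %", {
  errs <- sapply(1:5, function(s) {
    sp <- compression_spec(bvtv = sqrt(2000 / 15000),
                           noise_sigma = 0.01 * 300 * 2000 / 15000, seed = s)
    cc <- generate_compression_curve(sp)
    abs(modulus(normalize_curve(cc$record, cc$geometry))$modulus / 2000 - 1)
  })
  expect_lt(median(errs), 0.05)
})

test_that("toughness integrates stress over strain up to failure", {
  tri <- triangle_ss(eps_f = 0.05, s_f = 100)
  fl <- find_failure(tri, smooth = 1)
  expect_equal(toughness(tri, fl), 2.5, tolerance = 1e-12)  # half base x height
  flat <- as_ss(seq(0, 0.05, 0.001), rep(100, 51))
  expect_equal(pracma::trapz(flat$strain, flat$stress), 5.0)
  expect_error(toughness(as_ss(seq(0, 0.05, 0.001),
                               seq(0, 100, length.out = 51))),
               "clear")
  # trapezoid refinement converges on the smooth generator curve
  exact <- local({
    E <- 15000 * 0.09; sp <- 300 * 0.09
    e1 <- 0.8 * sp / E; ef <- 1.2 * sp / E; k <- E^2 / (0.8 * sp)
    E * e1^2 / 2 + sp * (ef - e1) - k * (ef - e1)^3 / 3
  })
  err <- sapply(c(1e-3, 1e-4), function(h) {
    abs(generate_compression_curve(
      compression_spec(0.3, strain_step = h)
    )$truth$toughness_mj_m3 - exact)
  })
  expect_lt(err[2], err[1] / 50)  # ~second-order convergence
})

test_that("the export table keeps included specimens and lists exclusions", {
  recs <- list(
    generate_compression_curve(compression_spec(0.2, seed = 1)),
    generate_compression_curve(compression_spec(0.3, seed = 2)),
    generate_compression_curve(compression_spec(0.25, post_peak_drop = 0,
                                                seed = 3))
  )
  sums <- do.call(rbind, lapply(seq_along(recs), function(i) {
    mechanics_summary(recs[[i]]$record, recs[[i]]$geometry,
                      specimen = paste0("s", i))
  }))
  bv <- tibble::tibble(specimen = c("s1", "s2", "s3"),
                       bvtv = c(0.2, 0.3, 0.25))
  grp <- c(s1 = "dry", s2 = "soaked", s3 = "rehydrated")
  cmp <- c(s1 = "I", s2 = "I", s3 = "II")
  out <- export_analysis_table(sums, bv, grp, cmp)
  expect_equal(nrow(out$table), 2)
  expect_equal(out$excluded$specimen, "s3")
  expect_match(out$excluded$reason, "clear peak")
  expect_equal(out$table$log_response, log(out$table$response))
  expect_equal(out$table$bvtv_sq, out$table$bvtv^2)
  expect_error(export_analysis_table(sums, bv[1:2, ], grp, cmp), "join")
})
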