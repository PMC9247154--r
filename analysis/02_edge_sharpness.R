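#!/usr/bin/env Rscript
# Edge-sharpness analysis: line profiles across the cortex of the tibia
# phantoms at each hydration state, fitted with the Gaussian-CDF edge model
# both raw and after the conditioning protocol (Savitzky-Golay span 9 +
# cubic-spline upsampling).
# Finding: raw fits recover the configured point-spread blur; conditioned
# fits are broader for sub-2-px edges (the documented smoothing cost), and
# the FWHM/sigma ratio equals the Gaussian constant 2.3548 for every fit.

suppressPackageStartupMessages(library(bonetomoqc))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (state in c("dry", "rehydrated_12h", "rehydrated_40h")) {
  ph <- generate_volume(tibia_phantom_spec(state, seed = 1L))
  # horizontal profile through the volume centre crossing both cortex walls
  prof <- extract_profile(ph$volume, 32, c(32, 2, 32, 63),
                          averaging_width = 11, units = "px")
  cond <- condition_profile(prof)
  win <- propose_edge_windows(cond, 0.35, half_width = 6)
  for (w in seq_len(nrow(win))) {
    fc <- fit_edge(cond, window = c(win$lo[w], win$hi[w]))
    fr <- fit_edge(prof, window = c(win$lo[w], win$hi[w]))
    if (!fc$converged || !fr$converged) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      state = state, edge = w, mu_px = fc$mu,
      sigma_raw_px = fr$sigma, sigma_cond_px = fc$sigma,
      fwhm_raw_px = fr$fwhm, fwhm_cond_px = fc$fwhm,
      nrmse_cond = fc$nrmse, fwhm_sigma_ratio = fc$fwhm / fc$sigma
    )
  }
}
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/edge_sharpness.csv", row.names = FALSE)
print(as.data.frame(tab), digits = 4)
message(sprintf(
  "%d edges fitted; configured blur %.2f px; median raw sigma %.2f px, median conditioned sigma %.2f px; FWHM/sigma uniformly %.4f",
  nrow(tab), 7 / 7.15, median(tab$sigma_raw_px), median(tab$sigma_cond_px),
  unique(round(tab$fwhm_sigma_ratio, 4))
))
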