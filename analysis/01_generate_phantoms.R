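#!/usr/bin/env Rscript
# Generate the synthetic study material: neutron-style plug volumes in three
# hydration states, tibia volumes in three hydration states, and an
# X-ray-style plug for morphometry. Volumes are written as multi-page TIFF
# with JSON sidecars under results/phantoms/ so later steps (and external
# viewers) can load them.

suppressPackageStartupMessages(library(bonetomoqc))

out_dir <- "results/phantoms"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

for (state in c("soaked", "dry", "rehydrated")) {
  ph <- generate_volume(plug_phantom_spec(state, seed = seed))
  write_volume(ph$volume, file.path(out_dir, sprintf("plug_%s.tif", state)),
    extra = list(
      state = state, seed = seed,
      phases = as.data.frame(ph$phases)
    )
  )
  message(sprintf("plug %-10s: %d voxels in specimen, phases: %s",
                  state, sum(ph$labels != 1L),
                  paste(ph$phases$label, collapse = ", ")))
}

for (state in c("dry", "rehydrated_12h", "rehydrated_40h")) {
  ph <- generate_volume(tibia_phantom_spec(state, seed = seed))
  write_volume(ph$volume, file.path(out_dir, sprintf("tibia_%s.tif", state)),
    extra = list(state = state, seed = seed,
                 phases = as.data.frame(ph$phases))
  )
  message(sprintf("tibia %-15s written", state))
}

ph <- generate_volume(xray_plug_spec(0.3, seed = seed))
write_volume(ph$volume, file.path(out_dir, "xray_plug_bvtv30.tif"),
  extra = list(
    seed = seed,
    achieved_bvtv = ph$phases$achieved_fraction[ph$phases$label == "bone"]
  )
)
message(sprintf(
  "xray plug written, achieved BV/TV %.4f",
  ph$phases$achieved_fraction[ph$phases$label == "bone"]
))
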