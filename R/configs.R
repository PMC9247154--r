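#' Neutron-style trabecular plug phantom, by hydration state
#'
#' Synthetic stand-in for a neutron tomography volume of a trabecular bone
#' plug in one of three hydration states. Grey values follow the dark-to-
#' bright phase ordering of neutron images (void < bone < marrow) and are
#' chosen once to emulate the qualitative state-to-state behaviour: the
#' soaked (control) state has no internal voids; the dry state has prominent
#' voids and a marrow mean pulled to within one noise-FWHM of the bone mean
#' (so the bone and marrow peaks merge); the rehydrated state has restored
#' bone/marrow contrast but residual voids. Noise defaults to the plug-scan
#' level of 1192 grey values; voxel size 15.6 um; point-spread sigma 12 um.
#'
#' @param state hydration state.
#' @param n cubic edge length in voxels.
#' @param noise_sigma grey-value noise SD.
#' @param seed RNG seed.
#' @return A [phantom_spec()].
#' @export
plug_phantom_spec <- function(state = c("soaked", "dry", "rehydrated"),
                              n = 64L, noise_sigma = 1192, seed = 1L) {
  state <- match.arg(state)
  cyl <- geom_cylinder(radius = 0.4 * n)
  greys <- switch(state,
    soaked = list(marrow = 43000, bone = 33000, void = NULL, void_frac = 0),
    dry = list(marrow = 34000, bone = 33000, void = 15000, void_frac = 0.12),
    rehydrated = list(marrow = 43000, bone = 33000, void = 15000,
                      void_frac = 0.08)
  )
  phases <- list(
    phantom_phase("background", geom_everything(), 4000),
    phantom_phase("marrow", cyl, greys$marrow),
    phantom_phase("bone",
      geom_rod_lattice(cyl, target_fraction = 0.3, rod_radius = 4,
                       jitter = 0.1),
      greys$bone
    )
  )
  if (greys$void_frac > 0) {
    phases <- c(phases, list(
      phantom_phase("void",
        geom_spheres(cyl, target_fraction = greys$void_frac,
                     sphere_radius = 6),
        greys$void
      )
    ))
  }
  phantom_spec(
    shape = c(n, n, n), voxel_size = 15.6, phases = phases,
    blur_sigma = 12, noise_sigma = noise_sigma, bit_depth = 16L, seed = seed
  )
}

#' Neutron-style rat tibia phantom, by hydration state
#'
#' Cross-section from the inside out: intramedullary canal, cortex, soft
#' tissue shell, background. In the final hydration state the canal holds
#' free liquid (D2O) whose grey value sits close to the cortex. State-to-
#' state grey values and noise are fixed once so that the cortex-background
#' CNR decreases with increasing rehydration and the free-liquid state has
#' the lowest liquid-cortex contrast; they emulate orderings, not absolute
#' values.
#'
#' @param state hydration state (`dry`, `rehydrated_12h`,
#'   `rehydrated_40h`; the last has free liquid in the canal).
#' @param n cubic edge length in voxels.
#' @param seed RNG seed.
#' @return A [phantom_spec()].
#' @export
tibia_phantom_spec <- function(state = c("dry", "rehydrated_12h",
                                         "rehydrated_40h"),
                               n = 64L, seed = 1L) {
  state <- match.arg(state)
  r_canal <- 0.18 * n
  r_cortex <- 0.30 * n
  r_soft <- 0.42 * n
  pars <- switch(state,
    dry = list(canal = 8000, cortex = 40000, soft = 47000, noise = 2250),
    rehydrated_12h = list(canal = 10000, cortex = 37000, soft = 48000,
                          noise = 2600),
    rehydrated_40h = list(canal = 34000, cortex = 36000, soft = 48000,
                          noise = 3000)
  )
  canal_label <- if (state == "rehydrated_40h") "d2o" else "canal"
  phases <- list(
    phantom_phase("background", geom_everything(), 4000),
    phantom_phase("soft_tissue", geom_cylinder(radius = r_soft), pars$soft),
    phantom_phase("cortex", geom_cylinder(radius = r_cortex), pars$cortex),
    phantom_phase(canal_label, geom_cylinder(radius = r_canal), pars$canal)
  )
  phantom_spec(
    shape = c(n, n, n), voxel_size = 7.15, phases = phases,
    blur_sigma = 7, noise_sigma = pars$noise, bit_depth = 16L, seed = seed
  )
}

#' X-ray-style trabecular plug phantom for BV/TV morphometry
#'
#' Bright bone on dark marrow, with grey values straddling the 16-bit bone
#' threshold interval 30375..65535 near its midpoint, at a voxel size of
#' 13.5 um. The rod radius (9 voxels ~ 240 um) matches the thick trabeculae
#' of bovine femoral bone at this resolution and keeps the radius-2 median
#' filter's curvature erosion small relative to the rod cross-section. The
#' achieved bone fraction of the rod lattice is recorded in the generated
#' phantom and serves as ground truth for BV/TV recovery.
#'
#' @param target_bvtv target bone volume fraction of the rod lattice.
#' @param n cubic edge length in voxels (the default accommodates a few
#'   lattice cells at every target fraction).
#' @param noise_sigma grey-value noise SD (default 2 percent of the
#'   bone-marrow contrast).
#' @param seed RNG seed.
#' @return A [phantom_spec()].
#' @export
xray_plug_spec <- function(target_bvtv, n = 144L, noise_sigma = 580,
                           seed = 1L) {
  cyl <- geom_cylinder(radius = 0.42 * n)
  phases <- list(
    phantom_phase("background", geom_everything(), 5000),
    phantom_phase("marrow", cyl, 16000),
    phantom_phase("bone",
      geom_rod_lattice(cyl, target_fraction = target_bvtv, rod_radius = 9,
                       jitter = 0.1),
      45000
    )
  )
  phantom_spec(
    shape = c(n, n, n), voxel_size = 13.5, phases = phases,
    blur_sigma = 10, noise_sigma = noise_sigma, bit_depth = 16L, seed = seed
  )
}

#' Two-phase half-volume phantom for edge-sharpness work
#'
#' A single planar boundary between two grey levels, blurred by a known
#' point-spread sigma: the simplest ground-truth edge for edge-spread-
#' function fitting.
#'
#' @param levels `(low, high)` grey values on either side of the boundary.
#' @param n cubic edge length in voxels.
#' @param blur_sigma_um point-spread sigma, micrometres.
#' @param noise_sigma grey-value noise SD.
#' @param voxel_size voxel size, micrometres.
#' @param seed RNG seed.
#' @return A [phantom_spec()] with the boundary at x = n/2 + 0.5.
#' @export
edge_phantom_spec <- function(levels = c(10000, 40000), n = 48L,
                              blur_sigma_um = 10, noise_sigma = 0,
                              voxel_size = 7.15, seed = 1L) {
  phases <- list(
    phantom_phase("low", geom_everything(), levels[1]),
    phantom_phase("high", geom_halfspace("x", at = n / 2 + 0.5), levels[2])
  )
  phantom_spec(
    shape = c(n, n, n), voxel_size = voxel_size, phases = phases,
    blur_sigma = blur_sigma_um, noise_sigma = noise_sigma, bit_depth = 16L,
    seed = seed
  )
}
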