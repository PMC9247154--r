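#' Phantom specification
#'
#' Declarative description of a synthetic specimen in reconstructed-image
#' space: an ordered list of phases (each a geometry primitive painted with a
#' mean grey value), a Gaussian point-spread blur of known sigma, and additive
#' Gaussian noise. Later phases overwrite earlier ones where primitives
#' overlap, so the phase order is the precedence rule.
#'
#' @param shape voxel counts per axis, `(nz, ny, nx)`.
#' @param voxel_size isotropic voxel size in micrometres.
#' @param phases list of [phantom_phase()] entries; the first phase must cover
#'   the whole volume (typically the background).
#' @param blur_sigma Gaussian point-spread sigma in micrometres (>= 0).
#' @param noise_sigma additive Gaussian noise SD in grey-value units (>= 0).
#' @param bit_depth grey-scale bit depth; grey values are clipped to its range
#'   after noise.
#' @param seed RNG seed; identical spec + seed gives bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, voxel_size, phases, blur_sigma = 0,
                         noise_sigma = 0, bit_depth = 16L, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (length(phases) < 1L) stop("at least one phase is required")
  labs <- vapply(phases, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("phase labels must be unique")
  structure(
    list(
      shape = as.integer(shape), voxel_size = voxel_size, phases = phases,
      blur_sigma = blur_sigma, noise_sigma = noise_sigma,
      bit_depth = as.integer(bit_depth), seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Phantom phase
#'
#' @param label phase name (e.g. "background", "cortex", "marrow").
#' @param geometry a geometry primitive (`geom_*()`).
#' @param mean mean grey value painted into the phase before blur and noise.
#' @export
phantom_phase <- function(label, geometry, mean) {
  stopifnot(is.character(label), length(label) == 1L)
  list(label = label, geometry = geometry, mean = mean)
}

# ---- geometry primitives ----------------------------------------------------

#' Geometry primitives for phantom phases
#'
#' All coordinates are in voxel units with voxel centres at integers,
#' `(z, y, x)` ordered. `geom_everything()` claims the full volume (use it for
#' the background base layer). Cylinders are z-aligned. `geom_rod_lattice()`
#' fills a region with three orthogonal families of rods on a regular lattice
#' with per-rod jittered radii; the base radius is solved by bisection so the
#' achieved volume fraction matches `target_fraction`, and the achieved value
#' is recorded in the generated phantom. `geom_spheres()` scatters random
#' spheres in a region until a target fraction is reached (used for voids).
#'
#' @param axis,at,side half-space: coordinate axis ("z","y","x"), threshold,
#'   and which side ("high" keeps coordinates >= `at`).
#' @param radius,center,r_inner,zlim cylinder: outer radius, `(y, x)` centre
#'   (defaults to the volume centre), inner radius (> 0 gives a hollow
#'   cylinder/shell), z range.
#' @param zlim,ylim,xlim box bounds (inclusive, voxel indices).
#' @param region containing primitive for lattice/sphere fills.
#' @param target_fraction target volume fraction within `region`, in \[0, 1\].
#' @param rod_radius base rod radius in voxels; lattice spacing is derived
#'   from it and the target fraction.
#' @param jitter relative SD of per-rod radius jitter.
#' @param sphere_radius radius of scattered void spheres (voxels).
#' @name geometry
NULL

#' @rdname geometry
#' @export
geom_everything <- function() structure(list(type = "everything"), class = "phantom_geom")

#' @rdname geometry
#' @export
geom_halfspace <- function(axis = c("x", "y", "z"), at, side = c("high", "low")) {
  structure(list(
    type = "halfspace", axis = match.arg(axis), at = at,
    side = match.arg(side)
  ), class = "phantom_geom")
}

#' @rdname geometry
#' @export
geom_cylinder <- function(radius, center = NULL, r_inner = 0, zlim = NULL) {
  stopifnot(radius > 0, r_inner >= 0, r_inner < radius)
  structure(list(
    type = "cylinder", radius = radius, center = center,
    r_inner = r_inner, zlim = zlim
  ), class = "phantom_geom")
}

#' @rdname geometry
#' @export
geom_sphere <- function(center, radius) {
  stopifnot(length(center) == 3L, radius > 0)
  structure(list(type = "sphere", center = center, radius = radius),
    class = "phantom_geom"
  )
}

#' @rdname geometry
#' @export
geom_box <- function(zlim, ylim, xlim) {
  structure(list(type = "box", zlim = zlim, ylim = ylim, xlim = xlim),
    class = "phantom_geom"
  )
}

#' @rdname geometry
#' @export
geom_rod_lattice <- function(region, target_fraction, rod_radius = 9,
                             jitter = 0.1) {
  if (target_fraction < 0 || target_fraction > 1) {
    stop("`target_fraction` must be in [0, 1]")
  }
  structure(list(
    type = "rod_lattice", region = region,
    target_fraction = target_fraction, rod_radius = rod_radius,
    jitter = jitter
  ), class = "phantom_geom")
}

#' @rdname geometry
#' @export
geom_spheres <- function(region, target_fraction, sphere_radius = 4) {
  if (target_fraction < 0 || target_fraction > 1) {
    stop("`target_fraction` must be in [0, 1]")
  }
  structure(list(
    type = "spheres", region = region,
    target_fraction = target_fraction, sphere_radius = sphere_radius
  ), class = "phantom_geom")
}

voxel_grids <- function(shape) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  list(
    z = array(rep(seq_len(nz), times = ny * nx), dim = shape),
    y = array(rep(rep(seq_len(ny), each = nz), times = nx), dim = shape),
    x = array(rep(seq_len(nx), each = nz * ny), dim = shape)
  )
}

# Evaluate a primitive to a logical mask. Stochastic primitives draw from the
# active RNG stream and report the achieved fraction within their region.
geom_mask <- function(g, grids, shape) {
  achieved <- NA_real_
  mask <- switch(g$type,
    everything = array(TRUE, dim = shape),
    halfspace = {
      co <- grids[[g$axis]]
      if (g$side == "high") co >= g$at else co < g$at
    },
    cylinder = {
      ctr <- g$center %||% c((shape[2] + 1) / 2, (shape[3] + 1) / 2)
      d2 <- (grids$y - ctr[1])^2 + (grids$x - ctr[2])^2
      m <- d2 <= g$radius^2 & d2 >= g$r_inner^2
      if (!is.null(g$zlim)) m <- m & grids$z >= g$zlim[1] & grids$z <= g$zlim[2]
      m
    },
    sphere = {
      (grids$z - g$center[1])^2 + (grids$y - g$center[2])^2 +
        (grids$x - g$center[3])^2 <= g$radius^2
    },
    box = {
      grids$z >= g$zlim[1] & grids$z <= g$zlim[2] &
        grids$y >= g$ylim[1] & grids$y <= g$ylim[2] &
        grids$x >= g$xlim[1] & grids$x <= g$xlim[2]
    },
    rod_lattice = {
      res <- rod_lattice_mask(g, grids, shape)
      achieved <- res$achieved
      res$mask
    },
    spheres = {
      res <- scattered_spheres_mask(g, grids, shape)
      achieved <- res$achieved
      res$mask
    },
    stop("unknown geometry primitive: ", g$type)
  )
  list(mask = mask, achieved = achieved)
}

# Squared distance to the nearest rod axis of one family, normalized by the
# per-rod jitter factor so membership for base radius r is just q < r^2.
rod_family_q <- function(u, v, spacing, jitter_mat) {
  off <- spacing / 2
  iu <- pmin(pmax(round((u - off) / spacing), 0), nrow(jitter_mat) - 1L)
  iv <- pmin(pmax(round((v - off) / spacing), 0), ncol(jitter_mat) - 1L)
  du <- u - (off + iu * spacing)
  dv <- v - (off + iv * spacing)
  jf <- jitter_mat[iu + nrow(jitter_mat) * iv + 1L]
  ((du^2 + dv^2) / jf^2)
}

rod_lattice_mask <- function(g, grids, shape) {
  region <- geom_mask(g$region, grids, shape)$mask
  n_region <- sum(region)
  if (n_region == 0L) stop("rod lattice region is empty")
  f <- g$target_fraction
  if (f == 0) return(list(mask = region & FALSE, achieved = 0))
  # per-family fraction p so that the union of three independent orthogonal
  # families has fraction f, then spacing from the base rod radius
  p <- 1 - (1 - f)^(1 / 3)
  spacing <- g$rod_radius * sqrt(pi / p)
  ncell <- ceiling(max(shape) / spacing) + 2L
  jit <- function() {
    matrix(pmax(1 + g$jitter * stats::rnorm(ncell * ncell), 0.2), ncell, ncell)
  }
  qz <- rod_family_q(grids$y, grids$x, spacing, jit())
  qy <- rod_family_q(grids$z, grids$x, spacing, jit())
  qx <- rod_family_q(grids$z, grids$y, spacing, jit())
  frac_at <- function(r) {
    r2 <- r^2
    sum((qz < r2 | qy < r2 | qx < r2) & region) / n_region
  }
  lo <- 0.25; hi <- spacing * 0.71
  for (i in seq_len(24)) {
    mid <- (lo + hi) / 2
    if (frac_at(mid) < f) lo <- mid else hi <- mid
  }
  r <- (lo + hi) / 2
  mask <- (qz < r^2 | qy < r^2 | qx < r^2) & region
  list(mask = mask, achieved = sum(mask) / n_region)
}

scattered_spheres_mask <- function(g, grids, shape) {
  region <- geom_mask(g$region, grids, shape)$mask
  n_region <- sum(region)
  if (n_region == 0L) stop("sphere fill region is empty")
  mask <- array(FALSE, dim = shape)
  r <- g$sphere_radius
  idx_region <- which(region)
  for (i in seq_len(2000L)) {
    if (sum(mask) / n_region >= g$target_fraction) break
    ctr_idx <- idx_region[sample.int(length(idx_region), 1L)]
    cz <- grids$z[ctr_idx]; cy <- grids$y[ctr_idx]; cx <- grids$x[ctr_idx]
    hit <- (grids$z - cz)^2 + (grids$y - cy)^2 + (grids$x - cx)^2 <= r^2
    mask <- mask | (hit & region)
  }
  list(mask = mask, achieved = sum(mask) / n_region)
}

# ---- volume generation ------------------------------------------------------

#' Generate a synthetic reconstructed tomographic volume
#'
#' Paints the phases of a [phantom_spec()] in declaration order (later phases
#' win where primitives overlap), applies a Gaussian point-spread blur of the
#' declared physical sigma (mirror boundary handling, so local means are
#' preserved at the faces), adds Gaussian noise, and clips to the bit-depth
#' range. The pre-blur integer label map is returned alongside the volume as
#' ground truth for morphometry, ROI placement, and histogram peaks.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom` with elements `volume` (a [volume()]),
#'   `labels` (integer array of phase indices), `phases` (tibble with label,
#'   mean, and achieved volume fraction for stochastic primitives), `spec`.
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    grids <- voxel_grids(spec$shape)
    label <- array(NA_integer_, dim = spec$shape)
    achieved <- rep(NA_real_, length(spec$phases))
    for (i in seq_along(spec$phases)) {
      gm <- geom_mask(spec$phases[[i]]$geometry, grids, spec$shape)
      label[gm$mask] <- i
      achieved[i] <- gm$achieved
    }
    if (anyNA(label)) {
      stop("configuration error: some voxels belong to no phase; ",
           "the first phase must cover the whole volume")
    }
    means <- vapply(spec$phases, `[[`, numeric(1), "mean")
    grey <- array(means[label], dim = spec$shape)
    if (spec$blur_sigma > 0) {
      sig_vox <- spec$blur_sigma / spec$voxel_size
      grey <- array(
        gaussian_blur3d_cpp(grey, dim(grey), rep(sig_vox, 3)),
        dim = dim(grey)
      )
    }
    if (spec$noise_sigma > 0) {
      grey <- grey + stats::rnorm(length(grey), 0, spec$noise_sigma)
    }
    gmax <- 2^spec$bit_depth - 1
    grey[grey < 0] <- 0
    grey[grey > gmax] <- gmax
    vol <- volume(grey, spec$voxel_size, spec$bit_depth,
      provenance = sprintf("phantom seed=%d", spec$seed)
    )
    phases <- tibble::tibble(
      phase = seq_along(spec$phases),
      label = vapply(spec$phases, `[[`, character(1), "label"),
      mean = means,
      achieved_fraction = achieved
    )
    structure(list(volume = vol, labels = label, phases = phases, spec = spec),
      class = "phantom"
    )
  })
}

#' Logical mask of one phantom phase
#'
#' @param phantom result of [generate_volume()].
#' @param label phase label.
#' @export
label_mask <- function(phantom, label) {
  stopifnot(inherits(phantom, "phantom"))
  i <- match(label, phantom$phases$label)
  if (is.na(i)) stop("no phase labelled '", label, "'")
  phantom$labels == i
}

# ---- 1D edge profile generator ---------------------------------------------

#' Generate a sampled edge-spread profile
#'
#' Samples `low + (high - low) * pnorm(x; mu, sigma)` plus Gaussian noise —
#' the Gaussian-CDF model of a blurred step edge whose derivative (the line
#' spread function) is a Gaussian of the same sigma.
#'
#' @param mu edge position.
#' @param sigma edge spread (> 0), same units as the abscissa.
#' @param levels numeric `(low, high)` plateau grey values.
#' @param n_points number of samples (>= 8).
#' @param noise_sigma additive Gaussian noise SD in grey units.
#' @param half_width half-extent of the abscissa around `mu`; defaults to
#'   `max(8 * sigma, 5)` so both plateaus are represented.
#' @param seed RNG seed for the noise (NULL leaves the RNG state alone).
#' @return A [line_profile()].
#' @export
generate_edge_profile <- function(mu, sigma, levels = c(0, 1), n_points = 81L,
                                  noise_sigma = 0, half_width = NULL,
                                  seed = NULL) {
  if (sigma <= 0) stop("`sigma` must be > 0")
  if (n_points < 8L) stop("`n_points` must be >= 8")
  half_width <- half_width %||% max(8 * sigma, 5)
  x <- seq(mu - half_width, mu + half_width, length.out = n_points)
  clean <- levels[1] + (levels[2] - levels[1]) * stats::pnorm(x, mu, sigma)
  noisy <- if (noise_sigma > 0) {
    draw <- function() clean + stats::rnorm(n_points, 0, noise_sigma)
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  } else {
    clean
  }
  line_profile(x, noisy, units = "px",
    source = sprintf("generated edge mu=%g sigma=%g", mu, sigma)
  )
}

# ---- compression curve generator -------------------------------------------

#' Synthetic compression-curve specification
#'
#' Intrinsic stress-strain behaviour of a trabecular bone plug as a function
#' of bone volume fraction: elastic modulus and peak stress scale with
#' `bvtv^2` (the standard power-law behaviour of trabecular bone), the curve
#' rises linearly to 80 % of the peak, rounds over a quadratic cap to the
#' peak, then softens linearly by `post_peak_drop` of the peak before
#' plateauing. With `post_peak_drop = 0` the curve is non-decreasing, which
#' exercises the downstream "no clear peak" exclusion rule.
#'
#' @param bvtv bone volume fraction in (0, 1].
#' @param modulus_scale modulus at BV/TV = 1, MPa (E = modulus_scale * bvtv^2).
#' @param strength_scale peak stress at BV/TV = 1, MPa.
#' @param post_peak_drop fraction of the peak stress lost in softening (>= 0).
#' @param noise_sigma Gaussian noise SD on stress, MPa (applied to force).
#' @param strain_max,strain_step strain grid extent and step.
#' @param diameter_mm,height_mm specimen geometry (defaults: plug cored with a
#'   6 mm drill and cut to 10 mm height).
#' @param displacement_rate_mm_s loading rate, metadata only.
#' @param seed RNG seed.
#' @export
compression_spec <- function(bvtv, modulus_scale = 15000, strength_scale = 300,
                             post_peak_drop = 0.3, noise_sigma = 0,
                             strain_max = 0.08, strain_step = 1e-4,
                             diameter_mm = 6, height_mm = 10,
                             displacement_rate_mm_s = 1, seed = 1L) {
  if (bvtv <= 0 || bvtv > 1) stop("`bvtv` must be in (0, 1]")
  if (diameter_mm <= 0 || height_mm <= 0) stop("geometry must be positive")
  if (post_peak_drop < 0 || post_peak_drop >= 1) {
    stop("`post_peak_drop` must be in [0, 1)")
  }
  structure(as.list(environment()), class = "compression_spec")
}

#' Generate a synthetic force-displacement compression record
#'
#' @param spec a [compression_spec()].
#' @return A list of class `compression_curve`: `record` (tibble with
#'   `time_s`, `force_N`, `displacement_mm`), `geometry`, and `truth` (the
#'   intrinsic modulus, peak stress, failure strain and toughness used to
#'   generate the curve).
#' @export
generate_compression_curve <- function(spec) {
  stopifnot(inherits(spec, "compression_spec"))
  E <- spec$modulus_scale * spec$bvtv^2
  sp <- spec$strength_scale * spec$bvtv^2
  eps1 <- 0.8 * sp / E
  epsf <- 1.2 * sp / E
  kcap <- E^2 / (0.8 * sp)
  eps <- seq(0, spec$strain_max, by = spec$strain_step)
  stress <- ifelse(eps <= eps1, E * eps,
    ifelse(eps <= epsf, sp - kcap * (epsf - eps)^2,
      if (spec$post_peak_drop > 0) {
        pmax(sp - (E / 3) * (eps - epsf), sp * (1 - spec$post_peak_drop))
      } else {
        sp
      }
    )
  )
  area_mm2 <- pi * spec$diameter_mm^2 / 4
  pre <- eps <= epsf
  truth <- list(
    modulus_mpa = E, peak_stress_mpa = sp, failure_strain = epsf,
    toughness_mj_m3 = pracma::trapz(eps[pre], stress[pre])
  )
  force <- stress * area_mm2
  if (spec$noise_sigma > 0) {
    force <- withr::with_seed(
      spec$seed,
      force + stats::rnorm(length(force), 0, spec$noise_sigma * area_mm2)
    )
  }
  disp <- eps * spec$height_mm
  record <- tibble::tibble(
    time_s = disp / spec$displacement_rate_mm_s,
    force_N = force,
    displacement_mm = disp
  )
  structure(
    list(
      record = record,
      geometry = list(diameter_mm = spec$diameter_mm, height_mm = spec$height_mm),
      truth = truth, spec = spec
    ),
    class = "compression_curve"
  )
}

# ---- weight series generator -----------------------------------------------

#' Synthetic drying/rehydration weight-series specification
#'
#' Exponential-approach kinetics: during drying the weight decays toward
#' `(1 - loss_fraction) * initial_weight` with rate `drying_rate`; during
#' rehydration it recovers toward `initial_weight` with rate
#' `rehydration_rate`. Defaults mirror a cohort that loses 10 % of its weight
#' with 97 % of the loss in the first 3 h, and regains 48.9 % of the lost
#' weight after 3 h of rehydration.
#'
#' @param initial_weight initial wet weight, g.
#' @param loss_fraction asymptotic fractional weight loss of drying.
#' @param drying_rate,rehydration_rate exponential rate constants, 1/h.
#' @param drying_duration drying time before rehydration starts, h.
#' @param sampling_times weighing times within each stage, h (>= 0).
#' @param noise_sigma weighing noise SD, g.
#' @param seed RNG seed.
#' @param specimen specimen id recorded in the log.
#' @export
weight_series_spec <- function(initial_weight = 0.85, loss_fraction = 0.10,
                               drying_rate = -log(0.03) / 3,
                               rehydration_rate = -log(1 - 0.489) / 3,
                               drying_duration = 3,
                               sampling_times = seq(0, 48, by = 3),
                               noise_sigma = 0, seed = 1L, specimen = "S1") {
  if (initial_weight <= 0) stop("`initial_weight` must be > 0")
  if (any(sampling_times < 0)) stop("sampling times must be >= 0")
  if (loss_fraction < 0 || loss_fraction > 1) {
    stop("`loss_fraction` must be in [0, 1]")
  }
  structure(as.list(environment()), class = "weight_series_spec")
}

weight_drying <- function(spec, t) {
  spec$initial_weight * (1 - spec$loss_fraction * (1 - exp(-spec$drying_rate * t)))
}

#' Generate a synthetic specimen weight log
#'
#' Produces an ordered weight log with stages `initial` (t = 0), `drying`
#' (sampling times up to the drying duration), `post-dry` (end of drying) and
#' `rehydration` (sampling times counted from the start of rehydration, with
#' `time_h` on the global clock).
#'
#' @param spec a [weight_series_spec()].
#' @return A tibble (`specimen`, `time_h`, `stage`, `weight_g`).
#' @export
generate_weight_series <- function(spec) {
  stopifnot(inherits(spec, "weight_series_spec"))
  td <- sort(unique(c(
    spec$sampling_times[spec$sampling_times > 0 &
      spec$sampling_times < spec$drying_duration],
    spec$drying_duration
  )))
  tr <- sort(unique(spec$sampling_times[spec$sampling_times > 0]))
  w_dry_end <- weight_drying(spec, spec$drying_duration)
  rows <- tibble::tibble(
    time_h = c(0, td, spec$drying_duration + tr),
    stage = c(
      "initial",
      ifelse(td == spec$drying_duration, "post-dry", "drying"),
      rep("rehydration", length(tr))
    ),
    weight_g = c(
      spec$initial_weight,
      weight_drying(spec, td),
      w_dry_end + (spec$initial_weight - w_dry_end) *
        (1 - exp(-spec$rehydration_rate * tr))
    )
  )
  if (spec$noise_sigma > 0) {
    rows$weight_g <- withr::with_seed(
      spec$seed,
      rows$weight_g + stats::rnorm(nrow(rows), 0, spec$noise_sigma)
    )
  }
  tibble::tibble(specimen = spec$specimen, rows)
}
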