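# Shared in-code fixtures for the test suite. Everything is generated at test
# time; nothing is read from disk.

# numeric vector with exactly the requested sample mean and (n-1) SD
exact_sample <- function(n, mean, sd, seed = 1) {
  withr::with_seed(seed, {
    x <- stats::rnorm(n)
    as.numeric(scale(x)) * sd + mean
  })
}

# plain two-phase volume split along x, no blur or noise unless asked
two_phase_volume <- function(n = 16, lo = 1000, hi = 3000, noise = 0,
                             seed = 1) {
  spec <- phantom_spec(
    shape = c(n, n, n), voxel_size = 1,
    phases = list(
      phantom_phase("low", geom_everything(), lo),
      phantom_phase("high", geom_halfspace("x", at = n / 2 + 0.5), hi)
    ),
    blur_sigma = 0, noise_sigma = noise, seed = seed
  )
  generate_volume(spec)
}

# wrap strain/stress vectors as a stress_strain record (bypassing normalize)
as_ss <- function(strain, stress) {
  out <- tibble::tibble(strain = strain, stress = stress)
  attr(out, "geometry") <- list(diameter_mm = 6, height_mm = 10)
  class(out) <- c("stress_strain", class(out))
  out
}

# triangle stress-strain curve: linear rise to (eps_f, s_f), linear drop after
triangle_ss <- function(eps_f = 0.05, s_f = 100, eps_end = 0.08,
                        step = 0.0025) {
  eps <- seq(0, eps_end, by = step)
  s <- ifelse(eps <= eps_f, s_f * eps / eps_f,
              s_f * (1 - 0.9 * (eps - eps_f) / (eps_end - eps_f)))
  as_ss(eps, s)
}

# weight log rows built by hand for hydration identities
manual_weight_log <- function(specimen = "s1", w0 = 10, w_dry = 9,
                              rehyd = data.frame(t = c(3, 6),
                                                 w = c(9.489, 9.7))) {
  tibble::tibble(
    specimen = specimen,
    time_h = c(0, 3, 3 + rehyd$t),
    stage = c("initial", "post-dry", rep("rehydration", nrow(rehyd))),
    weight_g = c(w0, w_dry, rehyd$w)
  )
}
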