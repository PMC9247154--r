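#' Normalize a force-displacement record to stress-strain
#'
#' Applies the preload convention: samples before the force first reaches the
#' preload are discarded and the displacement is re-zeroed at the preload
#' crossing (linearly interpolated between samples to remove sampling-grid
#' bias). Stress is force over the plug cross-section `pi d^2 / 4` (MPa with
#' N and mm), strain is displacement over specimen height.
#'
#' @param record data frame with `force_N` and `displacement_mm` (a `time_s`
#'   column is carried through if present).
#' @param geometry list with `diameter_mm` and `height_mm`; defaults to the
#'   Ø6 mm x 10 mm plug geometry.
#' @param preload_N preload threshold (default 15 N).
#' @return A tibble of class `stress_strain` with `strain` and `stress`
#'   (MPa), and attributes `geometry`, `preload_N`.
#' @export
normalize_curve <- function(record,
                            geometry = list(diameter_mm = 6, height_mm = 10),
                            preload_N = 15) {
  stopifnot(all(c("force_N", "displacement_mm") %in% names(record)))
  if (geometry$diameter_mm <= 0 || geometry$height_mm <= 0) {
    stop("geometry must be positive")
  }
  f <- record$force_N
  d <- record$displacement_mm
  if (length(f) != length(d)) stop("force and displacement lengths differ")
  i <- which(f >= preload_N)[1]
  if (is.na(i)) stop("preload not reached: force never attains ", preload_N, " N")
  if (i == 1L) {
    d0 <- d[1]
    keep_d <- d
    keep_f <- f
    first <- 1L
  } else {
    # linear interpolation of the crossing between samples i-1 and i
    w <- (preload_N - f[i - 1]) / (f[i] - f[i - 1])
    d0 <- d[i - 1] + w * (d[i] - d[i - 1])
    keep_d <- c(d0, d[i:length(d)])
    keep_f <- c(preload_N, f[i:length(f)])
    first <- i
  }
  area_mm2 <- pi * geometry$diameter_mm^2 / 4
  out <- tibble::tibble(
    strain = (keep_d - d0) / geometry$height_mm,
    stress = keep_f / area_mm2
  )
  if (any(diff(out$strain) < 0)) {
    stop("displacement must be non-decreasing after the preload crossing")
  }
  attr(out, "geometry") <- geometry
  attr(out, "preload_N") <- preload_N
  class(out) <- c("stress_strain", class(out))
  out
}

#' Find the failure point as the first clear peak
#'
#' Failure is the first local stress maximum whose drop on both sides exceeds
#' `prominence_frac` times the global maximum stress. Peak detection runs on
#' a lightly smoothed copy of the stress (centred moving average over
#' `smooth` samples) so that single-sample noise spikes on densely sampled
#' records are not mistaken for failure; the curve itself is not altered. A
#' record with no clear peak (e.g. monotone hardening) is flagged
#' `clear_peak = FALSE` and is to be excluded from downstream analysis
#' rather than assigned a failure point.
#'
#' @param ss a `stress_strain` record from [normalize_curve()] (>= 10
#'   samples).
#' @param prominence_frac clear-peak prominence threshold as a fraction of
#'   the global maximum stress.
#' @param smooth odd moving-average span (samples) for peak detection; 1
#'   disables smoothing.
#' @return A list with `clear_peak`, `failure_strain`, `peak_stress`,
#'   `index`.
#' @export
find_failure <- function(ss, prominence_frac = 0.05, smooth = 5L) {
  s <- ss$stress
  n <- length(s)
  if (n < 10L) stop("need at least 10 samples")
  if (smooth > 1L) s <- moving_avg(s, smooth)
  thr <- prominence_frac * max(s)
  cand <- which(s > c(-Inf, s[-n]) & s >= c(s[-1], -Inf) &
    seq_len(n) > 1L & seq_len(n) < n)
  for (i in cand) {
    higher_l <- which(s[seq_len(i - 1L)] > s[i])
    from <- if (length(higher_l)) max(higher_l) else 1L
    drop_l <- s[i] - min(s[from:i])
    right <- s[i:n]
    higher_r <- which(right > s[i])
    to <- if (length(higher_r)) min(higher_r) else length(right)
    drop_r <- s[i] - min(right[1:to])
    if (drop_l >= thr && drop_r >= thr) {
      return(list(
        clear_peak = TRUE, failure_strain = ss$strain[i],
        peak_stress = s[i], index = i
      ))
    }
  }
  list(clear_peak = FALSE, failure_strain = NA_real_, peak_stress = NA_real_,
       index = NA_integer_)
}

#' Elastic modulus from the linear portion of the stress-strain curve
#'
#' The modulus is the maximum least-squares slope over all sliding windows of
#' the given strain width within the pre-failure data. Taking the maximum
#' slope selects the linear portion automatically and excludes a concave-up
#' toe region. To avoid the selection bias of maximizing over many noisy
#' overlapping windows, the window is *selected* on a lightly smoothed copy
#' of the stress and the reported slope is then *estimated* from the raw data
#' in that window.
#'
#' @param ss a `stress_strain` record.
#' @param window_strain_width width of the sliding strain window.
#' @param end_strain upper strain bound of the search (defaults to the
#'   failure strain when a clear peak exists, otherwise the full record).
#' @param smooth odd moving-average span (samples) used only for window
#'   selection; 1 disables smoothing. The default scales with the sampling
#'   density to roughly one window of samples.
#' @return A list with `modulus` (MPa) and `window` (strain interval used).
#' @export
modulus <- function(ss, window_strain_width = 0.005, end_strain = NULL,
                    smooth = NULL) {
  if (is.null(end_strain)) {
    fl <- find_failure(ss)
    end_strain <- if (fl$clear_peak) fl$failure_strain else max(ss$strain)
  }
  keep <- ss$strain <= end_strain
  x <- ss$strain[keep]; y <- ss$stress[keep]
  if (length(x) < 2L || diff(range(x)) < window_strain_width) {
    stop("insufficient pre-failure data for a window of width ",
         window_strain_width)
  }
  n <- length(x)
  if (is.null(smooth)) {
    step <- stats::median(diff(x))
    smooth <- max(1L, round(window_strain_width / step))
    if (smooth %% 2L == 0L) smooth <- smooth + 1L
  }
  ysel <- if (smooth > 1L && n > smooth) moving_avg(y, smooth) else y
  best <- -Inf; best_i <- NA_integer_; best_j <- NA_integer_
  j <- 1L
  for (i in seq_len(n)) {
    if (x[n] - x[i] < window_strain_width) break
    while (j < n && x[j + 1L] <= x[i] + window_strain_width) j <- j + 1L
    if (j - i + 1L < 4L) next
    xc <- x[i:j] - mean(x[i:j])
    slope <- sum(xc * ysel[i:j]) / sum(xc^2)
    if (slope > best) {
      best <- slope
      best_i <- i; best_j <- j
    }
  }
  if (!is.finite(best)) stop("no valid modulus window found")
  xc <- x[best_i:best_j] - mean(x[best_i:best_j])
  list(
    modulus = sum(xc * y[best_i:best_j]) / sum(xc^2),
    window = c(x[best_i], x[best_j])
  )
}

#' Toughness as the area under the stress-strain curve to failure
#'
#' Trapezoidal integral of stress with respect to strain from zero strain to
#' the failure strain. In MPa times dimensionless strain this is numerically
#' MJ/m^3.
#'
#' @param ss a `stress_strain` record.
#' @param failure result of [find_failure()]; computed internally if `NULL`.
#' @return Toughness in MJ/m^3.
#' @export
toughness <- function(ss, failure = NULL) {
  if (is.null(failure)) failure <- find_failure(ss)
  if (!isTRUE(failure$clear_peak)) {
    stop("toughness requires a clear failure peak")
  }
  keep <- ss$strain <= failure$failure_strain
  pracma::trapz(ss$strain[keep], ss$stress[keep])
}

#' Summarize one compression test
#'
#' Runs [normalize_curve()], [find_failure()], [modulus()] and [toughness()]
#' on one force-displacement record and returns a one-row summary. Records
#' without a clear peak get `NA` mechanical parameters and
#' `clear_peak = FALSE`.
#'
#' @param record force-displacement data frame.
#' @param geometry,preload_N see [normalize_curve()].
#' @param prominence_frac see [find_failure()].
#' @param window_strain_width see [modulus()].
#' @param specimen specimen id carried into the summary.
#' @return A one-row tibble: `specimen`, `clear_peak`, `peak_stress`,
#'   `failure_strain`, `modulus`, `toughness`, `modulus_window_lo/hi`.
#' @export
mechanics_summary <- function(record,
                              geometry = list(diameter_mm = 6, height_mm = 10),
                              preload_N = 15, prominence_frac = 0.05,
                              window_strain_width = 0.005,
                              specimen = NA_character_) {
  ss <- normalize_curve(record, geometry, preload_N)
  fl <- find_failure(ss, prominence_frac)
  if (fl$clear_peak) {
    mod <- modulus(ss, window_strain_width, end_strain = fl$failure_strain)
    tgh <- toughness(ss, fl)
    tibble::tibble(
      specimen = specimen, clear_peak = TRUE,
      peak_stress = fl$peak_stress, failure_strain = fl$failure_strain,
      modulus = mod$modulus, toughness = tgh,
      modulus_window_lo = mod$window[1], modulus_window_hi = mod$window[2]
    )
  } else {
    tibble::tibble(
      specimen = specimen, clear_peak = FALSE,
      peak_stress = NA_real_, failure_strain = NA_real_,
      modulus = NA_real_, toughness = NA_real_,
      modulus_window_lo = NA_real_, modulus_window_hi = NA_real_
    )
  }
}

#' Assemble the tidy analysis-export table
#'
#' Joins mechanical summaries with BV/TV results and specimen metadata into
#' the table handed to external statistics software: one row per included
#' specimen with the chosen response, its natural log, BV/TV, (BV/TV)^2,
#' hydration group and experimental campaign. Specimens without a clear peak
#' are excluded and listed with the reason.
#'
#' @param summaries tibble of [mechanics_summary()] rows.
#' @param bvtv_results data frame with `specimen` and `bvtv`.
#' @param groups named character vector: hydration group per specimen.
#' @param campaigns named character vector: campaign label per specimen.
#' @param response which mechanical parameter is the response variable.
#' @return A list with `table` (tibble: specimen, response, log_response,
#'   bvtv, bvtv_sq, group, campaign) and `excluded` (tibble: specimen,
#'   reason).
#' @export
export_analysis_table <- function(summaries, bvtv_results, groups, campaigns,
                                  response = c("peak_stress", "modulus",
                                               "toughness")) {
  response <- match.arg(response)
  ids <- summaries$specimen
  if (!all(ids %in% bvtv_results$specimen)) {
    stop("join error: specimens missing from BV/TV results: ",
         paste(setdiff(ids, bvtv_results$specimen), collapse = ", "))
  }
  if (!all(ids %in% names(groups)) || !all(ids %in% names(campaigns))) {
    stop("join error: specimens missing group or campaign labels")
  }
  excluded <- summaries[!summaries$clear_peak, "specimen", drop = FALSE]
  excluded <- tibble::tibble(
    specimen = excluded$specimen,
    reason = rep("no clear peak", nrow(excluded))
  )
  inc <- summaries[summaries$clear_peak, ]
  bv <- bvtv_results$bvtv[match(inc$specimen, bvtv_results$specimen)]
  resp <- inc[[response]]
  tab <- tibble::tibble(
    specimen = inc$specimen,
    response = resp,
    log_response = log(resp),
    bvtv = bv,
    bvtv_sq = bv^2,
    group = unname(groups[inc$specimen]),
    campaign = unname(campaigns[inc$specimen])
  )
  list(table = tab, excluded = excluded)
}
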