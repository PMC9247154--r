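#' Region-of-interest grey-value sample
#'
#' A labelled rectangular ROI extracted from one or more transverse slices of
#' a volume. ROIs are the unit of the contrast-to-noise analysis: each holds
#' the grey values of a single material phase (background, cortex, D2O, soft
#' tissue, marrow, void).
#'
#' @param v a [volume()].
#' @param label phase name.
#' @param slice slice index (or vector of indices) along z.
#' @param box list with `y = c(lo, hi)` and `x = c(lo, hi)` pixel bounds
#'   (inclusive).
#' @param min_voxels minimum ROI size; smaller ROIs give unstable SD
#'   estimates and are rejected.
#' @return An object of class `roi_sample`.
#' @export
roi_sample <- function(v, label, slice, box, min_voxels = 30L) {
  stopifnot(inherits(v, "volume"))
  d <- dim(v$data)
  if (any(slice < 1) || any(slice > d[1])) stop("slice index out of range")
  if (box$y[1] < 1 || box$y[2] > d[2] || box$x[1] < 1 || box$x[2] > d[3]) {
    stop("ROI box outside the volume")
  }
  vals <- as.vector(v$data[slice, box$y[1]:box$y[2], box$x[1]:box$x[2]])
  if (length(vals) < min_voxels) {
    stop(sprintf(
      "insufficient sample: ROI '%s' has %d voxels (< %d)",
      label, length(vals), min_voxels
    ))
  }
  structure(
    list(label = label, slice = slice, box = box, values = vals,
         n = length(vals)),
    class = "roi_sample"
  )
}

#' Build an ROI sample directly from grey values
#'
#' For ROIs whose voxels were collected elsewhere (e.g. from a label-map
#' mask).
#'
#' @param label phase name.
#' @param values grey values.
#' @param min_voxels minimum sample size.
#' @export
roi_from_values <- function(label, values, min_voxels = 30L) {
  if (length(values) < min_voxels) {
    stop(sprintf(
      "insufficient sample: ROI '%s' has %d voxels (< %d)",
      label, length(values), min_voxels
    ))
  }
  structure(
    list(label = label, slice = NA_integer_, box = NULL,
         values = as.numeric(values), n = length(values)),
    class = "roi_sample"
  )
}

#' Estimate image noise from a background ROI
#'
#' The noise level of a reconstructed volume, estimated as the sample
#' standard deviation of the grey values in a region containing only
#' background.
#'
#' @param roi a background [roi_sample()].
#' @return The grey-value SD.
#' @export
estimate_noise <- function(roi) {
  stopifnot(inherits(roi, "roi_sample"))
  if (roi$label != "background") {
    stop("noise must be estimated from an ROI labelled 'background'")
  }
  stats::sd(roi$values)
}

#' Contrast-to-noise ratio between two ROIs
#'
#' `CNR = |mean(S1) - mean(S2)| / sqrt(sd(S1)^2 + sd(S2)^2)` with sample
#' (n - 1) standard deviations. Symmetric under swapping the ROIs. If both
#' SDs are zero the result is 0 for equal means (no contrast, no noise) and
#' flagged infinite for unequal means (degenerate noiseless contrast).
#'
#' @param s1,s2 [roi_sample()] objects.
#' @return An object of class `cnr_result` with the pair, the CNR, per-ROI
#'   means/SDs/sizes, and a `degenerate` flag.
#' @export
cnr <- function(s1, s2) {
  stopifnot(inherits(s1, "roi_sample"), inherits(s2, "roi_sample"))
  m1 <- mean(s1$values); m2 <- mean(s2$values)
  sd1 <- stats::sd(s1$values); sd2 <- stats::sd(s2$values)
  denom <- sqrt(sd1^2 + sd2^2)
  degenerate <- FALSE
  if (denom == 0) {
    if (m1 == m2) {
      value <- 0
    } else {
      value <- Inf
      degenerate <- TRUE
    }
  } else {
    value <- abs(m1 - m2) / denom
  }
  structure(
    list(
      pair = c(s1$label, s2$label), cnr = value,
      mean1 = m1, mean2 = m2, sd1 = sd1, sd2 = sd2,
      n1 = s1$n, n2 = s2$n, degenerate = degenerate
    ),
    class = "cnr_result"
  )
}

#' @export
print.cnr_result <- function(x, ...) {
  cat(sprintf(
    "<cnr_result> %s vs %s: CNR = %.3f%s\n",
    x$pair[1], x$pair[2], x$cnr, if (x$degenerate) " (degenerate)" else ""
  ))
  invisible(x)
}

parse_pairs <- function(pairs) {
  if (is.character(pairs)) pairs <- strsplit(pairs, ":", fixed = TRUE)
  lapply(pairs, function(p) {
    if (length(p) != 2L) stop("each pair must name exactly two labels")
    p
  })
}

#' Contrast-to-noise panel over representative slices
#'
#' Computes the CNR for every requested phase pair in every configured slice
#' and aggregates across slices (mean and sample SD), the way CNR panels are
#' reported over a handful of representative slices per specimen and state.
#'
#' @param v a [volume()].
#' @param rois a data frame with columns `label`, `slice`, `ymin`, `ymax`,
#'   `xmin`, `xmax` declaring one rectangular ROI per phase per slice.
#' @param pairs list of label pairs (`c("cortex", "background")`) or strings
#'   (`"cortex:background"`).
#' @param min_voxels minimum ROI size.
#' @return A list with `per_slice` (tibble: pair, slice, cnr, means, sds, n)
#'   and `aggregate` (tibble: pair, mean/SD of the per-slice CNRs).
#' @export
cnr_panel <- function(v, rois, pairs, min_voxels = 30L) {
  rois <- tibble::as_tibble(rois)
  pairs <- parse_pairs(pairs)
  wanted <- unique(unlist(pairs))
  missing <- setdiff(wanted, rois$label)
  if (length(missing) > 0) {
    stop("configuration error: no ROI declared for label(s) ",
         paste(missing, collapse = ", "))
  }
  rows <- list()
  for (p in pairs) {
    sl <- intersect(
      rois$slice[rois$label == p[1]], rois$slice[rois$label == p[2]]
    )
    if (length(sl) == 0) {
      stop("configuration error: labels ", p[1], " and ", p[2],
           " share no slice")
    }
    for (k in sl) {
      get_roi <- function(lab) {
        r <- rois[rois$label == lab & rois$slice == k, ][1, ]
        roi_sample(v, lab, k,
          box = list(y = c(r$ymin, r$ymax), x = c(r$xmin, r$xmax)),
          min_voxels = min_voxels
        )
      }
      res <- cnr(get_roi(p[1]), get_roi(p[2]))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pair = paste(p, collapse = ":"), slice = k, cnr = res$cnr,
        mean1 = res$mean1, mean2 = res$mean2, sd1 = res$sd1, sd2 = res$sd2,
        n1 = res$n1, n2 = res$n2
      )
    }
  }
  per_slice <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_slice, per_slice$pair), function(d) {
    tibble::tibble(
      pair = d$pair[1], cnr_mean = mean(d$cnr),
      cnr_sd = if (nrow(d) > 1) stats::sd(d$cnr) else NA_real_,
      n_slices = nrow(d)
    )
  }))
  rownames(agg) <- NULL
  list(per_slice = per_slice, aggregate = agg)
}
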