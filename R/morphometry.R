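#' Instrument threshold presets for bone segmentation
#'
#' Named 16-bit grey-value intervals for bone: `"next"` = 30375..65535 and
#' `"4dlab"` = 53500..65535, after the two X-ray setups they calibrate.
#'
#' @export
bvtv_threshold_presets <- function() {
  list(
    "next" = c(30375, 65535),
    "4dlab" = c(53500, 65535)
  )
}

#' Threshold segmentation of bone
#'
#' Boolean mask of voxels whose grey value lies in `[low, high]` (inclusive
#' ends). Use a named instrument preset or a custom interval.
#'
#' @param v a [volume()] (typically median-filtered first).
#' @param interval numeric `(low, high)`; ignored if `preset` is given.
#' @param preset preset name, see [bvtv_threshold_presets()].
#' @return A logical array with the interval recorded in attribute
#'   `threshold`.
#' @export
threshold_segment <- function(v, interval = NULL, preset = NULL) {
  stopifnot(inherits(v, "volume"))
  if (!is.null(preset)) {
    presets <- bvtv_threshold_presets()
    if (!preset %in% names(presets)) {
      stop("unknown preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "))
    }
    interval <- presets[[preset]]
  }
  if (is.null(interval) || length(interval) != 2L) {
    stop("provide `interval = c(low, high)` or a `preset` name")
  }
  if (interval[1] > interval[2]) stop("inverted threshold interval")
  mask <- v$data >= interval[1] & v$data <= interval[2]
  attr(mask, "threshold") <- interval
  mask
}

#' Bone volume fraction
#'
#' `BV/TV = (bone voxels within the specimen mask) / (specimen voxels)`. The
#' total volume is the specimen mask (not the whole image), since plug
#' specimens do not fill the field of view.
#'
#' @param bone_mask logical array from [threshold_segment()].
#' @param spec_mask logical array from [specimen_mask()] (or ground truth).
#' @param filter_radius,threshold optional metadata recorded in the result.
#' @return An object of class `bvtv_result`.
#' @export
bvtv <- function(bone_mask, spec_mask, filter_radius = NA_integer_,
                 threshold = attr(bone_mask, "threshold")) {
  if (!identical(dim(bone_mask), dim(spec_mask))) {
    stop("masks must have the same shape")
  }
  total <- sum(spec_mask)
  if (total == 0) stop("empty specimen mask")
  bone <- sum(bone_mask & spec_mask)
  structure(
    list(
      bvtv = bone / total, bone_voxels = bone, total_voxels = total,
      threshold = threshold %||% c(NA_real_, NA_real_),
      filter_radius = filter_radius
    ),
    class = "bvtv_result"
  )
}

#' @export
print.bvtv_result <- function(x, ...) {
  cat(sprintf(
    "<bvtv_result> BV/TV = %.4f (%d / %d voxels), threshold [%s, %s], median radius %s\n",
    x$bvtv, x$bone_voxels, x$total_voxels,
    format(x$threshold[1]), format(x$threshold[2]), format(x$filter_radius)
  ))
  invisible(x)
}

#' Full BV/TV morphometry pipeline
#'
#' Median filter (radius 2 by default), instrument-preset global threshold,
#' background-excluding specimen mask, and the resulting bone volume
#' fraction.
#'
#' @param v a [volume()].
#' @param preset threshold preset name (default `"next"`); or supply
#'   `interval`.
#' @param interval custom threshold interval.
#' @param radius median filter radius.
#' @param spec_mask optional precomputed specimen mask; computed with
#'   [specimen_mask()] from the filtered volume when `NULL`.
#' @return A `bvtv_result`.
#' @export
bvtv_pipeline <- function(v, preset = "next", interval = NULL, radius = 2L,
                          spec_mask = NULL) {
  filt <- median_filter_volume(v, radius)
  bone <- threshold_segment(filt, interval = interval,
    preset = if (is.null(interval)) preset else NULL
  )
  if (is.null(spec_mask)) spec_mask <- specimen_mask(filt)
  bvtv(bone, spec_mask, filter_radius = radius)
}
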