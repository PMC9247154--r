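#' Percent weight change
#'
#' `C = (w_after - w_initial) / w_initial * 100`: the relative weight change
#' of a specimen across a drying or rehydration step, in percent (negative
#' for loss).
#'
#' @param w_initial initial weight, g (> 0).
#' @param w_after weight after the step, g.
#' @return Percent change (vectorized).
#' @export
percent_change <- function(w_initial, w_after) {
  if (any(w_initial <= 0)) stop("`w_initial` must be > 0")
  (w_after - w_initial) / w_initial * 100
}

log_stage_weight <- function(log, stage_name) {
  rows <- log[log$stage == stage_name, ]
  if (nrow(rows) == 0) return(NULL)
  rows
}

#' Fraction of lost weight regained during rehydration
#'
#' `100 * (w(t) - w_dry) / (w_initial - w_dry)` where `t` is counted from the
#' start of rehydration; weights between weighings are linearly interpolated,
#' since the log only holds discrete weighings.
#'
#' @param log weight log for one specimen: tibble with `time_h` (global
#'   clock), `stage` in `initial` / `drying` / `post-dry` / `rehydration`,
#'   `weight_g`.
#' @param at_time rehydration time in hours (from the post-dry weighing).
#' @return Percent of the lost weight regained at `at_time`.
#' @export
fraction_regained <- function(log, at_time) {
  ini <- log_stage_weight(log, "initial")
  dry <- log_stage_weight(log, "post-dry")
  reh <- log_stage_weight(log, "rehydration")
  if (is.null(ini) || is.null(dry)) {
    stop("log must contain 'initial' and 'post-dry' events")
  }
  w0 <- ini$weight_g[1]
  wd <- dry$weight_g[nrow(dry)]
  t_dry <- dry$time_h[nrow(dry)]
  if (w0 == wd) stop("no weight was lost: fraction regained is undefined")
  if (at_time < 0) stop("`at_time` must be >= 0")
  if (at_time == 0) return(0)
  if (is.null(reh)) stop("log contains no rehydration events")
  tr <- reh$time_h - t_dry
  wr <- reh$weight_g
  # anchor the series at the post-dry weight (t = 0)
  tr <- c(0, tr); wr <- c(wd, wr)
  if (at_time > max(tr)) {
    stop("`at_time` lies beyond the last rehydration weighing")
  }
  w_t <- stats::approx(tr, wr, xout = at_time)$y
  100 * (w_t - wd) / (w0 - wd)
}

#' Cohort summary of percent weight change
#'
#' Per-specimen percent change from the initial weight to the requested
#' stage, aggregated as mean and sample (n - 1) SD, matching mean +/- SD
#' reporting. Specimens missing the stage are listed as excluded rather than
#' failing the summary.
#'
#' @param logs list of per-specimen weight logs, or one tibble with a
#'   `specimen` column.
#' @param stage stage to evaluate (`"post-dry"` or `"rehydration"`).
#' @param at_time for `stage = "rehydration"`, the rehydration time in hours
#'   (interpolated); the last rehydration weighing when `NULL`.
#' @return A list with `mean`, `sd`, `n`, `per_specimen` (tibble: specimen,
#'   percent_change) and `excluded` (character vector).
#' @export
cohort_summary <- function(logs, stage = "post-dry", at_time = NULL) {
  if (is.data.frame(logs)) logs <- split(logs, logs$specimen)
  per <- list()
  excluded <- character(0)
  for (nm in names(logs)) {
    log <- logs[[nm]]
    id <- if ("specimen" %in% names(log)) log$specimen[1] else nm
    ini <- log_stage_weight(log, "initial")
    if (is.null(ini)) {
      excluded <- c(excluded, id)
      next
    }
    w0 <- ini$weight_g[1]
    w_after <- if (stage == "rehydration") {
      reh <- log_stage_weight(log, "rehydration")
      dry <- log_stage_weight(log, "post-dry")
      if (is.null(reh) || is.null(dry)) {
        NULL
      } else if (is.null(at_time)) {
        reh$weight_g[nrow(reh)]
      } else {
        t_dry <- dry$time_h[nrow(dry)]
        tr <- c(0, reh$time_h - t_dry)
        wr <- c(dry$weight_g[nrow(dry)], reh$weight_g)
        if (at_time > max(tr)) NULL else stats::approx(tr, wr, xout = at_time)$y
      }
    } else {
      rows <- log_stage_weight(log, stage)
      if (is.null(rows)) NULL else rows$weight_g[nrow(rows)]
    }
    if (is.null(w_after)) {
      excluded <- c(excluded, id)
      next
    }
    per[[length(per) + 1L]] <- tibble::tibble(
      specimen = id, percent_change = percent_change(w0, w_after)
    )
  }
  if (length(per) < 2L) {
    stop("insufficient sample: need at least 2 logs with stage '", stage, "'")
  }
  per <- do.call(rbind, per)
  list(
    mean = mean(per$percent_change),
    sd = stats::sd(per$percent_change),
    n = nrow(per),
    per_specimen = per,
    excluded = excluded
  )
}
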