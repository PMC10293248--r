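#' Clip the start and end of a time-ordered series
#'
#' Dropping and lifting the pen produce high-variance artefacts at the edges
#' of a recording, so time-dependent features are computed after removing
#' the first and last `fraction` of the data points. `floor(fraction * n)`
#' samples are removed from each end; order is preserved.
#'
#' @param series Vector, or data frame whose rows are time-ordered samples.
#' @param fraction Proportion to clip per end, in `[0, 0.5)`; default 0.10.
#' @return The clipped series of the same type.
#' @export
clip_time_series <- function(series, fraction = 0.10) {
  if (fraction < 0 || fraction >= 0.5) {
    stop("domain error: fraction must be in [0, 0.5)")
  }
  n <- if (is.data.frame(series)) nrow(series) else length(series)
  if (n == 0L) stop("validation error: empty series")
  k <- floor(fraction * n)
  idx <- seq.int(k + 1L, n - k)
  if (is.data.frame(series)) {
    out <- series[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    series[idx]
  }
}

#' Remove the largest-magnitude values as outliers
#'
#' Pen slips inflate the extremes of time-independent summaries (e.g. the
#' mean distance to the spiral), so the top `fraction` of values with the
#' highest magnitude are removed before summarising:
#' `k = floor(fraction * n)` values with the largest `|value|` are dropped,
#' treating inward and outward slips symmetrically. The remaining values
#' keep their original order.
#'
#' @param values Numeric vector.
#' @param fraction Proportion to remove, default 0.05.
#' @return `values` with the `k` largest-magnitude entries removed.
#' @export
remove_top_values <- function(values, fraction = 0.05) {
  n <- length(values)
  if (n == 0L) stop("validation error: empty input")
  if (fraction < 0 || fraction >= 1) {
    stop("domain error: fraction must be in [0, 1)")
  }
  k <- floor(fraction * n)
  if (k == 0L) return(values)
  drop_idx <- order(abs(values), decreasing = TRUE)[seq_len(k)]
  values[-drop_idx]
}

#' Combine the two repetition values of a feature
#'
#' Each arm draws the spiral twice; the two per-repetition feature values
#' are combined by their arithmetic mean. A single available repetition
#' passes through unchanged.
#'
#' @param v1,v2 Per-repetition feature values (scalar; `NA` if missing).
#' @return The repetition mean.
#' @export
combine_repetitions <- function(v1, v2 = NA_real_) {
  if (is.na(v1) && is.na(v2)) {
    stop("validation error: both repetitions missing")
  }
  mean(c(v1, v2), na.rm = TRUE)
}

#' Select the stronger-affected arm
#'
#' The arm whose clipped distance-to-spiral series has the larger
#' (repetition-averaged, population) standard deviation is taken as the
#' stronger affected side; its features feed the analysis. Ties break to the
#' right arm (deterministic). A side with no recordings loses by default
#' with a warning.
#'
#' @param left,right Lists of [signed_distance_series()] objects (one per
#'   repetition) for each arm; may be empty for at most one side.
#' @param clip_fraction Edge-clip fraction applied before the SD, default 0.10.
#' @return Object of class `arm_selection`: list with `chosen`
#'   (`"left"`/`"right"`), `left_std`, `right_std` (cm).
#' @export
select_affected_arm <- function(left, right, clip_fraction = 0.10) {
  side_sd <- function(series_list) {
    if (length(series_list) == 0L) return(NA_real_)
    vals <- vapply(series_list, function(s) {
      pop_sd(clip_time_series(s$d, clip_fraction))
    }, numeric(1))
    mean(vals)
  }
  left_std <- side_sd(left)
  right_std <- side_sd(right)
  if (is.na(left_std) && is.na(right_std)) {
    stop("validation error: no distance series on either side")
  }
  if (is.na(left_std) || is.na(right_std)) {
    warning("one side has no recordings; selecting the other by default")
    chosen <- if (is.na(left_std)) "right" else "left"
  } else if (left_std > right_std) {
    chosen <- "left"
  } else {
    chosen <- "right"  # ties break to the right
  }
  structure(list(chosen = chosen, left_std = left_std,
                 right_std = right_std),
            class = "arm_selection")
}
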