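#' Questionnaire yes-count (QYes)
#'
#' @param q A [questionnaire_response()].
#' @return Integer in `[0, 30]`: the number of items answered yes.
#' @export
qyes <- function(q) {
  stopifnot(inherits(q, "questionnaire_response"))
  sum(q$items)
}

#' Spectral configuration for the tremor-band laterality feature
#'
#' The distance-series spectrum is restricted to the tremor-relevant band
#' and aggregated into equal-width bins before taking the across-bin
#' standard deviation.
#'
#' @param f_lo,f_hi Band edges in Hz (defaults 3 and 15).
#' @param n_bins Number of equal-width bins (default 20).
#' @return Object of class `spectral_config`.
#' @export
spectral_config <- function(f_lo = 3, f_hi = 15, n_bins = 20) {
  if (!(f_lo < f_hi)) stop("domain error: f_lo must be below f_hi")
  if (n_bins < 2) stop("domain error: n_bins must be >= 2")
  structure(list(f_lo = f_lo, f_hi = f_hi, n_bins = n_bins),
            class = "spectral_config")
}

#' Velocity time series of a recording (Eq.-style discrete differentiation)
#'
#' `v_i = sqrt((x_i - x_{i-1})^2 + (y_i - y_{i-1})^2) / (t_i - t_{i-1})`,
#' with the first element defined as 0 (it has no predecessor). Duplicated
#' timestamps with identical position are dropped with a warning; a
#' duplicated timestamp with a different position is an error (infinite
#' velocity).
#'
#' @param rec A [drawing_recording()].
#' @return Data frame with columns `t` (s) and `v` (cm/s), `v[1] == 0`.
#' @export
velocity_series <- function(rec) {
  stopifnot(inherits(rec, "drawing_recording"))
  s <- rec$samples
  dt <- diff(s$t)
  if (any(dt == 0)) {
    dup <- which(dt == 0) + 1L
    moved <- s$x[dup] != s$x[dup - 1L] | s$y[dup] != s$y[dup - 1L]
    if (any(moved)) {
      stop(sprintf("validation error: repeated timestamp with distinct position at row %d",
                   dup[moved][1L]))
    }
    warning(sprintf("dropping %d duplicate-timestamp sample(s)", length(dup)))
    s <- s[-dup, , drop = FALSE]
    dt <- diff(s$t)
  }
  step <- sqrt(diff(s$x)^2 + diff(s$y)^2)
  data.frame(t = s$t, v = c(0, step / dt))
}

# magnitude spectrum of a distance series on a uniform grid:
# linear interpolation to the nominal rate, FFT, one-sided magnitudes
# scaled by 1/n so a sinusoid of amplitude A shows magnitude ~A/2
distance_spectrum <- function(d_series, rate = 240) {
  t <- d_series$t
  span <- t[length(t)] - t[1L]
  if (span <= 0) stop("validation error: zero-duration distance series")
  grid <- seq(t[1L], t[length(t)], by = 1 / rate)
  du <- approx(t, d_series$d, xout = grid, ties = "ordered")$y
  n <- length(du)
  mag <- Mod(fft(du)) / n
  nyq <- floor(n / 2)
  data.frame(freq = (seq_len(nyq + 1L) - 1L) * rate / n,
             mag = mag[seq_len(nyq + 1L)])
}

# per-side spectral statistic: band-restricted, binned magnitude spectrum
# and its across-bin (population) standard deviation
fft_bin_profile <- function(d_series, cfg = spectral_config(), rate = 240) {
  t <- d_series$t
  span <- t[length(t)] - t[1L]
  if (span < 1 / cfg$f_lo) {
    stop(sprintf("validation error: series shorter than one %g Hz period",
                 cfg$f_lo))
  }
  if (nrow(d_series) < 64L) {
    stop("validation error: distance series needs >= 64 samples for the spectrum")
  }
  spec <- distance_spectrum(d_series, rate)
  inband <- spec$freq >= cfg$f_lo & spec$freq <= cfg$f_hi
  edges <- seq(cfg$f_lo, cfg$f_hi, length.out = cfg$n_bins + 1L)
  bin <- cut(spec$freq[inband], breaks = edges, include.lowest = TRUE,
             labels = FALSE)
  vals <- vapply(seq_len(cfg$n_bins), function(b) {
    m <- spec$mag[inband][bin == b]
    if (length(m) == 0L) 0 else mean(m)
  }, numeric(1))
  list(bins = vals,
       bin_centers = (edges[-1L] + edges[-length(edges)]) / 2,
       bin_std = pop_sd(vals))
}

#' Tremor-band spectral laterality (F1c DistanceFFT)
#'
#' For each side, an FFT of the (clipped) distance-to-spiral series is
#' reduced to the 3–15 Hz band, quantised into 20 equal-width bins (mean
#' magnitude per bin), and the standard deviation across the 20 bin values
#' is computed as a dominant-frequency statistic. The feature is the
#' absolute difference of the two sides' bin standard deviations —
#' a laterality measure.
#'
#' @param left,right A `distance_series` (or list of them, one per
#'   repetition: repetitions are first averaged) per side, already
#'   edge-clipped.
#' @param cfg A [spectral_config()].
#' @param rate Uniform resampling rate in Hz before the FFT (default 240).
#' @return `|std_left - std_right|`.
#' @export
f1c_distance_fft <- function(left, right, cfg = spectral_config(),
                             rate = 240) {
  side_std <- function(side) {
    if (inherits(side, "distance_series") || is.data.frame(side)) {
      side <- list(side)
    }
    mean(vapply(side, function(s) fft_bin_profile(s, cfg, rate)$bin_std,
                numeric(1)))
  }
  abs(side_std(left) - side_std(right))
}

#' Precision features F2–F4 from a distance series
#'
#' `F2 MaxDistance` is the maximal magnitude of the deviation, `F3
#' MeanDistance` the mean magnitude, and `F4 StdDevDistance` the population
#' standard deviation of the signed series. Expects the top-5% magnitude
#' outlier removal ([remove_top_values()]) to have been applied already.
#'
#' @param d Numeric vector of signed distances (cm) after outlier removal.
#' @return Named vector `c(F2, F3, F4)` in cm.
#' @export
precision_features <- function(d) {
  if (length(d) == 0L) stop("validation error: empty distance series")
  c(F2 = max(abs(d)), F3 = mean(abs(d)), F4 = pop_sd(d))
}

# sign changes in consecutive nonzero differences; zero steps are skipped
count_direction_changes <- function(v) {
  dv <- diff(v)
  dv <- dv[dv != 0]
  if (length(dv) < 2L) return(0L)
  s <- sign(dv)
  sum(s[-1L] != s[-length(s)])
}

#' Direction-change counts F5–F7
#'
#' `F5 ChangeOfRadiusDirection` counts shifts of the radius from increasing
#' to decreasing and vice versa — a perfect spiral has a steadily
#' increasing radius, and tremor raises the count, making F5 an indirect
#' frequency measure. `F6`/`F7` apply the same count to the x and y
#' coordinate alone. Zero differences are skipped.
#'
#' @param rec A [drawing_recording()], already edge-clipped.
#' @param center Spiral centre for the radius, default `c(0, 0)`.
#' @return Named integer vector `c(F5, F6, F7)`.
#' @export
direction_change_features <- function(rec, center = c(0, 0)) {
  stopifnot(inherits(rec, "drawing_recording"))
  if (nrow(rec$samples) < 3L) {
    stop("validation error: need >= 3 samples to count direction changes")
  }
  r <- sqrt((rec$samples$x - center[1])^2 + (rec$samples$y - center[2])^2)
  c(F5 = count_direction_changes(r),
    F6 = count_direction_changes(rec$samples$x),
    F7 = count_direction_changes(rec$samples$y))
}

#' Force features F8–F10
#'
#' Mean, population standard deviation and median of the stylus force
#' series (dimensionless; 1 = average input).
#'
#' @param rec A [drawing_recording()] (edge-clipped), or a numeric force
#'   vector.
#' @return Named vector `c(F8, F9, F10)`.
#' @export
force_features <- function(rec) {
  force <- if (inherits(rec, "drawing_recording")) rec$samples$force else rec
  if (length(force) == 0L) stop("validation error: empty force series")
  c(F8 = mean(force), F9 = pop_sd(force), F10 = median(force))
}

#' Time and velocity features F11–F13
#'
#' `F11 TimeOfDrawing` is the total drawing time of the unclipped
#' recording. `F12 MeanVelocity` and `F13 StdDevVelocity` are the mean and
#' the square root of the population (divide-by-N) variance of the velocity
#' series of the edge-clipped recording, including the defined zero first
#' element.
#'
#' @param rec A [drawing_recording()] (unclipped).
#' @param clip_fraction Edge-clip fraction for the velocity series.
#' @return Named vector `c(F11, F12, F13)` (s, cm/s, cm/s).
#' @export
time_velocity_features <- function(rec, clip_fraction = 0.10) {
  stopifnot(inherits(rec, "drawing_recording"))
  f11 <- rec$samples$t[nrow(rec$samples)] - rec$samples$t[1L]
  if (f11 <= 0) stop("validation error: zero-duration recording")
  clipped <- drawing_recording(rec$participant_id, rec$hand, rec$repetition,
                               clip_time_series(rec$samples, clip_fraction),
                               rec$nominal_rate)
  v <- velocity_series(clipped)$v
  c(F11 = f11, F12 = mean(v), F13 = pop_sd(v))
}

#' Natural-log transform for visualisation
#'
#' Drawing-task features span orders of magnitude and erroneous extremes
#' dominate linear axes, so boxplots use `log(value + eps)`. Visualisation
#' only — the classifier consumes untransformed features.
#'
#' @param values Non-negative feature values.
#' @param eps Offset guarding `log(0)`, default 1e-9.
#' @return `log(values + eps)`.
#' @export
log_transform_features <- function(values, eps = 1e-9) {
  if (any(values < 0, na.rm = TRUE)) {
    stop("domain error: log transform expects non-negative feature values")
  }
  log(values + eps)
}

#' Canonical feature column names
#' @return Character vector: QYes plus the 13 motor feature names.
#' @export
feature_names <- function() {
  c("QYes", "F1c_DistanceFFT", "F2_MaxDistance", "F3_MeanDistance",
    "F4_StdDevDistance", "F5_ChangeOfRadiusDirection",
    "F6_ChangesOfDirectionX", "F7_ChangesOfDirectionY", "F8_MeanForce",
    "F9_StDevForce", "F10_MedianForce", "F11_TimeOfDrawing",
    "F12_MeanVelocity", "F13_StdDevVelocity")
}

# all per-repetition quantities for one recording
repetition_features <- function(rec, template, cfg, clip_fraction = 0.10,
                                top_fraction = 0.05) {
  rec <- ensure_outward(rec, template$center)
  dfull <- signed_distance_series(rec, template)
  clipped_samples <- clip_time_series(rec$samples, clip_fraction)
  rec_clip <- drawing_recording(rec$participant_id, rec$hand, rec$repetition,
                                clipped_samples, rec$nominal_rate)
  d_clip <- structure(
    clip_time_series(as.data.frame(dfull), clip_fraction),
    class = c("distance_series", "data.frame"))
  d_trim <- remove_top_values(dfull$d, top_fraction)
  prec <- precision_features(d_trim)
  dirs <- direction_change_features(rec_clip, template$center)
  frc <- force_features(rec_clip)
  tim <- time_velocity_features(rec, clip_fraction)
  list(
    values = c(prec, dirs, frc, tim),
    bin_std = fft_bin_profile(d_clip, cfg, rec$nominal_rate)$bin_std,
    clip_sd = pop_sd(d_clip$d),
    d_clip = d_clip
  )
}

#' Extract the full feature vector of a participant
#'
#' Composition: direction check, distance series, edge clipping
#' (time-dependent context) and top-magnitude outlier removal
#' (time-independent context) per recording; per-repetition features are
#' averaged within each arm; the arm with the larger repetition-averaged
#' distance SD (the stronger affected side) supplies F2–F13, while
#' `F1c DistanceFFT` consumes both arms as a laterality measure; QYes is
#' the questionnaire yes-count.
#'
#' @param p A [participant_record()] with both hands recorded.
#' @param template A [make_reference_spiral()] template.
#' @param cfg A [spectral_config()].
#' @param clip_fraction,top_fraction Preprocessing proportions (defaults
#'   0.10 per end and 0.05).
#' @return One-row tibble: participant_id, group, demographics, QYes and
#'   F1c–F13.
#' @export
extract_feature_vector <- function(p, template = make_reference_spiral(),
                                   cfg = spectral_config(),
                                   clip_fraction = 0.10,
                                   top_fraction = 0.05) {
  stopifnot(inherits(p, "participant_record"))
  hands <- vapply(p$recordings, `[[`, "", "hand")
  if (!all(c("left", "right") %in% hands)) {
    stop(sprintf("validation error: participant %s lacks both hands",
                 p$participant_id))
  }
  reps <- lapply(p$recordings, repetition_features, template = template,
                 cfg = cfg, clip_fraction = clip_fraction,
                 top_fraction = top_fraction)
  per_arm <- lapply(c(left = "left", right = "right"), function(h) {
    rr <- reps[hands == h]
    vals <- do.call(rbind, lapply(rr, `[[`, "values"))
    list(values = colMeans(vals),
         bin_std = mean(vapply(rr, `[[`, numeric(1), "bin_std")),
         clip_sd = mean(vapply(rr, `[[`, numeric(1), "clip_sd")))
  })
  sel <- select_affected_arm(
    lapply(reps[hands == "left"], `[[`, "d_clip"),
    lapply(reps[hands == "right"], `[[`, "d_clip"),
    clip_fraction
  )
  motor <- per_arm[[sel$chosen]]$values
  f1c <- abs(per_arm$left$bin_std - per_arm$right$bin_std)
  out <- tibble::tibble(
    participant_id = p$participant_id, group = p$group, age = p$age,
    gender = p$gender,
    hoehn_yahr = if (is.null(p$hoehn_yahr)) NA_real_ else p$hoehn_yahr,
    affected_arm = sel$chosen,
    QYes = qyes(p$questionnaire),
    F1c_DistanceFFT = f1c,
    F2_MaxDistance = motor[["F2"]],
    F3_MeanDistance = motor[["F3"]],
    F4_StdDevDistance = motor[["F4"]],
    F5_ChangeOfRadiusDirection = motor[["F5"]],
    F6_ChangesOfDirectionX = motor[["F6"]],
    F7_ChangesOfDirectionY = motor[["F7"]],
    F8_MeanForce = motor[["F8"]],
    F9_StDevForce = motor[["F9"]],
    F10_MedianForce = motor[["F10"]],
    F11_TimeOfDrawing = motor[["F11"]],
    F12_MeanVelocity = motor[["F12"]],
    F13_StdDevVelocity = motor[["F13"]]
  )
  out
}

#' Extract the feature table of a whole cohort
#'
#' @param cohort A [cohort_dataset()].
#' @inheritParams extract_feature_vector
#' @return Tibble with one row per participant (metadata + QYes + F1c–F13).
#' @export
extract_features <- function(cohort, template = make_reference_spiral(),
                             cfg = spectral_config(), clip_fraction = 0.10,
                             top_fraction = 0.05) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  rows <- lapply(cohort$participants, function(p) {
    tryCatch(
      extract_feature_vector(p, template, cfg, clip_fraction, top_fraction),
      error = function(e) {
        stop(sprintf("feature extraction failed for participant %s: %s",
                     p$participant_id, conditionMessage(e)))
      })
  })
  do.call(rbind, unname(rows))
}
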