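#' Reference Archimedean spiral template
#'
#' The drawing template is an Archimedean spiral r(theta) = b * theta with
#' pitch `b = max_radius / (2 * pi * n_loops)`, so after `n_loops` full turns
#' the radius is exactly `max_radius`. The study template has a maximal
#' radius of 3.75 cm and four loops.
#'
#' @param max_radius Maximal radius in cm (default 3.75).
#' @param n_loops Number of loops (default 4).
#' @param center Spiral centre `(cx, cy)` in cm.
#' @return Object of class `spiral_template` with fields `max_radius`,
#'   `n_loops`, `pitch_b` (cm per radian) and `center`.
#' @export
make_reference_spiral <- function(max_radius = 3.75, n_loops = 4,
                                  center = c(0, 0)) {
  if (!is.numeric(max_radius) || max_radius <= 0) {
    stop("domain error: max_radius must be positive")
  }
  if (!is.numeric(n_loops) || n_loops < 1) {
    stop("domain error: n_loops must be >= 1")
  }
  structure(
    list(max_radius = max_radius, n_loops = n_loops,
         pitch_b = max_radius / (2 * pi * n_loops),
         center = as.numeric(center)),
    class = "spiral_template"
  )
}

#' Template radius at an unwrapped angle
#'
#' @param template A [make_reference_spiral()] template.
#' @param theta Unwrapped angle(s) in radians.
#' @return Radius in cm, `pitch_b * theta`.
#' @export
spiral_radius <- function(template, theta) template$pitch_b * theta

#' Sample points on the template spiral
#'
#' Convenience generator of the ideal trajectory, used by tests and the
#' synthetic cohort: x = cx + b*theta*cos(theta), y = cy + b*theta*sin(theta).
#'
#' @param template A spiral template.
#' @param theta Vector of unwrapped angles.
#' @return Data frame with columns `x`, `y`.
#' @export
spiral_points <- function(template, theta) {
  r <- spiral_radius(template, theta)
  data.frame(x = template$center[1] + r * cos(theta),
             y = template$center[2] + r * sin(theta))
}

#' Unwrapped polar angle of a drawn trajectory
#'
#' Computes the continuous (unwrapped) polar angle of each sample about the
#' template centre. Successive angle differences are wrapped into
#' (-pi, pi] and accumulated, so a trajectory that keeps circling outward
#' yields a monotone angle ending near `2 * pi * n_loops`. Samples at the
#' centre itself (radius below 1e-6 cm), where the polar angle is
#' undefined, inherit the previous sample's angle (the first sample
#' defaults to angle 0); everywhere else atan2 is exact and the wrapped
#' differencing absorbs noise, so no wider guard band is needed — a wider
#' band would break the exactness of the ideal-template fixed point.
#'
#' @param rec A [drawing_recording()].
#' @param template A spiral template (supplies the centre).
#' @return Numeric vector of unwrapped angles (radians), one per sample.
#' @export
unwrap_angle <- function(rec, template) {
  stopifnot(inherits(rec, "drawing_recording"))
  dx <- rec$samples$x - template$center[1]
  dy <- rec$samples$y - template$center[2]
  r <- sqrt(dx^2 + dy^2)
  if (all(r < 0.05)) {
    stop("validation error: all samples at the spiral centre")
  }
  raw <- atan2(dy, dx)
  # carry the previous angle across exact-centre samples (atan2 undefined)
  near <- r < 1e-6
  if (near[1L]) raw[1L] <- 0
  if (any(near[-1L])) {
    for (i in which(near[-1L]) + 1L) raw[i] <- raw[i - 1L]
  }
  d <- diff(raw)
  d <- ((d + pi) %% (2 * pi)) - pi
  raw[1L] + c(0, cumsum(d))
}

#' Signed radial distance to the template spiral
#'
#' Transforms a drawn trajectory into the signed distance-to-spiral time
#' series: `d_i = r_i - b * theta_i`, the drawn radius minus the template
#' radius at the drawn point's unwrapped angle. Negative values mean the pen
#' was inside the template spiral (lower radius); an ideally traced template
#' maps to the all-zero series. This radial definition (rather than
#' nearest-point Euclidean distance) is what gives the series its sign.
#'
#' @param rec A [drawing_recording()].
#' @param template A spiral template.
#' @return Object of class `distance_series`: data frame with columns `t`
#'   (seconds) and `d` (signed cm), one row per sample.
#' @export
signed_distance_series <- function(rec, template) {
  theta <- unwrap_angle(rec, template)
  dx <- rec$samples$x - template$center[1]
  dy <- rec$samples$y - template$center[2]
  d <- sqrt(dx^2 + dy^2) - spiral_radius(template, theta)
  structure(data.frame(t = rec$samples$t, d = d),
            class = c("distance_series", "data.frame"))
}

#' Enforce outward (centre-to-rim) drawing direction
#'
#' The assessment expects spirals drawn from the centre outward; recordings
#' drawn rim-to-centre are reversed. The direction check compares the mean
#' radius over the first versus last 10% of samples (robust to start/end
#' jitter). On reversal the sample order is flipped and timestamps are
#' remapped as `t'_i = t_last - t_(n-1-i)` so durations, and hence
#' velocities, are preserved. Idempotent.
#'
#' @param rec A [drawing_recording()].
#' @param center Spiral centre, default `c(0, 0)`.
#' @return A [drawing_recording()], reversed if it was drawn inward.
#' @export
ensure_outward <- function(rec, center = c(0, 0)) {
  stopifnot(inherits(rec, "drawing_recording"))
  r <- sqrt((rec$samples$x - center[1])^2 + (rec$samples$y - center[2])^2)
  n <- length(r)
  k <- max(1L, floor(0.1 * n))
  if (mean(r[seq_len(k)]) <= mean(r[seq.int(n - k + 1L, n)])) {
    return(rec)
  }
  samples <- rec$samples[n:1, , drop = FALSE]
  samples$t <- rec$samples$t[n] - rev(rec$samples$t) + rec$samples$t[1L]
  rownames(samples) <- NULL
  drawing_recording(rec$participant_id, rec$hand, rec$repetition, samples,
                    rec$nominal_rate)
}
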