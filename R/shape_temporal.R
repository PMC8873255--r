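#' First- and second-order turning angles of a path
#'
#' A segment is treated as a sequence of movement vectors between
#' consecutive location samples.  At interior sample `i` the first-order
#' turning angle is the counterclockwise rotation from the incoming vector
#' `x[i-1] -> x[i]` to the outgoing vector `x[i] -> x[i+1]`, expressed in
#' degrees in `[0, 360)` so that clockwise turns land beyond 180.  The
#' second-order angle is defined the same way on the stride-2 vectors
#' `x[i-2] -> x[i]` and `x[i] -> x[i+2]`, which smooths over single-sample
#' localisation noise.  Consecutive duplicate points (zero-length vectors,
#' for which the angle is undefined) are merged before computing angles.
#'
#' @param xy n x 2 matrix of planar coordinates (metres).
#' @return A list of class `mm_angles` with `theta1` (degrees, one per
#'   interior point of the deduplicated path), `theta2` (one per point
#'   where both stride-2 vectors exist) and `theta_avg`, the per-point mean
#'   of the absolute (folded to `[0, 180]`) first- and second-order angles
#'   at the points where both are defined.  All empty when fewer than 3
#'   distinct points remain.
#' @export
turning_angles <- function(xy) {
  keep <- c(TRUE, rowSums(abs(diff(xy))) > 0)
  xy <- xy[keep, , drop = FALSE]
  n <- nrow(xy)
  empty <- list(theta1 = numeric(0), theta2 = numeric(0),
                theta_avg = numeric(0))
  class(empty) <- "mm_angles"
  if (n < 3) return(empty)
  ccw_angle <- function(v1, v2) {
    a <- atan2(v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1],
               v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2]) * 180 / pi
    a %% 360
  }
  d1 <- diff(xy)                       # v_i = x[i] -> x[i+1]
  theta1 <- ccw_angle(d1[1:(n - 2), , drop = FALSE],
                      d1[2:(n - 1), , drop = FALSE])
  theta2 <- numeric(0)
  if (n >= 5) {
    d2 <- xy[-(1:2), , drop = FALSE] - xy[1:(n - 2), , drop = FALSE]
    theta2 <- ccw_angle(d2[1:(n - 4), , drop = FALSE],
                        d2[-(1:2), , drop = FALSE])
  }
  fold <- function(a) pmin(a, 360 - a)
  theta_avg <- if (length(theta2) > 0) {
    (fold(theta1[2:(n - 3)]) + fold(theta2)) / 2
  } else numeric(0)
  structure(list(theta1 = theta1, theta2 = theta2, theta_avg = theta_avg),
            class = "mm_angles")
}

#' Segment complexity (tortuosity count)
#'
#' The number of interior points whose averaged absolute turning angle
#' \eqn{\theta_i = (|\theta^1_i| + |\theta^2_i|)/2} exceeds the threshold.
#' Because absolute angles are used, complexity is invariant to reversing
#' the direction of travel, and the first/second-order averaging damps
#' isolated localisation noise.
#'
#' @param angles An `mm_angles` object from [turning_angles()].
#' @param threshold Degrees (default 120, exploratory).
#' @return Nonnegative integer count.
#' @export
segment_complexity <- function(angles, threshold = 120) {
  sum(angles$theta_avg > threshold)
}

#' Total turning angle
#'
#' The sum of sines of the first-order turning angles,
#' \eqn{\sum_i \sin \theta^1_i}.  With angles in `[0, 360)` the sine is
#' negative beyond 180 degrees, so clockwise-majority turning yields a
#' negative total; unlike complexity this feature involves no threshold.
#'
#' @param angles An `mm_angles` object.
#' @return Signed dimensionless real.
#' @export
total_turning_angle <- function(angles) {
  sum(sin(angles$theta1 * pi / 180))
}

#' Radius of gyration of a point set
#'
#' Root-mean-square distance of the samples from their centroid; a scale
#' measure of the spatial extent of a segment.
#'
#' @param xy n x 2 matrix of planar coordinates (metres).
#' @return Metres.
#' @export
radius_of_gyration <- function(xy) {
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  sqrt(mean((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2))
}

#' Detect stops (static periods) within a segment
#'
#' A person is considered static when the location does not change for at
#' least `min_stop_duration`; under GPS jitter "does not change" is
#' operationalised as staying within `static_radius` of the stop's anchor
#' point.  Greedy scan: anchor at the current sample, extend the window
#' while every sample stays within `static_radius` of the anchor; if the
#' window spans at least `min_stop_duration` record its duration and
#' resume after it, otherwise advance one sample.
#'
#' @param xy n x 2 matrix of planar coordinates (metres).
#' @param time Numeric vector of sample times (seconds).
#' @param static_radius Metres (default 10, the same spatial scale as the
#'   segment endpoint slack).
#' @param min_stop_duration Seconds (default 60).
#' @return A list with `durations` (ordered stop durations in seconds) and
#'   `count`.
#' @export
detect_stops <- function(xy, time, static_radius = 10,
                         min_stop_duration = 60) {
  n <- length(time)
  durations <- numeric(0)
  i <- 1L
  while (i < n) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    out <- which(d2[(i + 1):n] > static_radius^2)
    last <- if (length(out) == 0) n else i + out[1] - 1L
    span <- time[last] - time[i]
    if (span >= min_stop_duration) {
      durations <- c(durations, span)
      i <- last + 1L
    } else {
      i <- i + 1L
    }
  }
  list(durations = durations, count = length(durations))
}
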