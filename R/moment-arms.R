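#' Joint-axis line
#'
#' An infinite line through a point (usually the anatomical joint centre)
#' with a unit direction: one of the three joint axes about which moment
#' arms are measured.
#'
#' @param point 3-point on the line (mm).
#' @param direction 3-vector; normalised internally, must be non-zero.
#' @return An object of class `axis_line` with unit `direction`.
#' @export
axis_line <- function(point, direction) {
  point <- as.numeric(point)
  stopifnot(length(point) == 3L, length(direction) == 3L)
  structure(list(point = point, direction = unitize(as.numeric(direction))),
            class = "axis_line")
}

#' Straight muscle line of action
#'
#' The muscle's force line, running from the proximal to the distal
#' implanted marker (or attachment point). The force direction is defined
#' proximal to distal; swapping the two points flips the sign of every
#' moment arm computed from the line.
#'
#' @param p_prox,p_dist 3-points (mm); must be at least `eps` apart.
#' @param eps Minimum separation (default 1e-6 mm).
#' @return An object of class `muscle_line` with elements `p_prox`,
#'   `p_dist` and unit `direction`.
#' @export
muscle_line <- function(p_prox, p_dist, eps = 1e-6) {
  p_prox <- as.numeric(p_prox); p_dist <- as.numeric(p_dist)
  stopifnot(length(p_prox) == 3L, length(p_dist) == 3L)
  d <- p_dist - p_prox
  len <- sqrt(sum(d^2))
  if (len <= eps) {
    stop("muscle markers are coincident (separation ", format(len),
         " mm); a muscle line needs two distinct points", call. = FALSE)
  }
  structure(list(p_prox = p_prox, p_dist = p_dist, direction = d / len),
            class = "muscle_line")
}

#' Common perpendicular between two lines
#'
#' The vector moment arm: the shortest segment joining two skew lines,
#' which is perpendicular to both. For intersecting lines the segment is
#' zero-length at the intersection; parallel lines admit infinitely many
#' perpendiculars, one of which is returned and the result flagged
#' degenerate.
#'
#' @param a,b `axis_line` objects (a `muscle_line` is accepted for `b`).
#' @param tol Parallelism tolerance on `|u x v|` (default 1e-9).
#' @return A list of class `vector_moment_arm`: `r_vec` (3-vector from the
#'   foot on `a` to the foot on `b`, mm), `length` (mm), `foot_axis`,
#'   `foot_muscle` (3-points) and `degenerate` (`TRUE` for parallel lines).
#' @export
common_perpendicular <- function(a, b, tol = 1e-9) {
  if (inherits(b, "muscle_line")) b <- axis_line(b$p_prox, b$direction)
  stopifnot(inherits(a, "axis_line"), inherits(b, "axis_line"))
  u <- a$direction; v <- b$direction
  w <- b$point - a$point
  n <- cross3(u, v)
  n2 <- sum(n^2)
  if (n2 < tol^2) {
    # parallel: any perpendicular; drop the component of w along u
    foot_a <- a$point
    foot_b <- b$point - sum(w * v) * v
    r <- foot_b - foot_a
    return(structure(list(r_vec = r, length = sqrt(sum(r^2)),
                          foot_axis = foot_a, foot_muscle = foot_b,
                          degenerate = TRUE), class = "vector_moment_arm"))
  }
  # closest-approach parameters from the standard two-line system
  d1 <- sum(u * v)
  su <- (sum(w * u) - d1 * sum(w * v)) / (1 - d1^2)
  sv <- (d1 * sum(w * u) - sum(w * v)) / (1 - d1^2)
  foot_a <- a$point + su * u
  foot_b <- b$point + sv * v
  r <- foot_b - foot_a
  structure(list(r_vec = r, length = sqrt(sum(r^2)),
                 foot_axis = foot_a, foot_muscle = foot_b,
                 degenerate = FALSE), class = "vector_moment_arm")
}

#' @export
print.vector_moment_arm <- function(x, ...) {
  cat("Vector moment arm: |r| =", format(x$length), "mm",
      if (x$degenerate) "(degenerate: parallel lines)", "\n")
  invisible(x)
}

#' Signed scalar moment arm of a muscle about one joint axis
#'
#' The geometric method: the vector moment arm `r` is the common
#' perpendicular between the joint axis and the muscle line; its magnitude
#' is then scaled by the fraction of the muscle direction lying in the
#' plane perpendicular to the axis (the only part able to generate a moment
#' about it), and signed by the right-hand-rule direction of the moment the
#' muscle force produces about the axis:
#' `sign((r x F_hat) . axis) * |r| * |F_hat - (F_hat . axis) axis|`.
#' The result equals the torque per unit force about the axis, in mm, and
#' is invariant to which point of the muscle line is used.
#'
#' @param axis An `axis_line` (unit direction).
#' @param muscle A `muscle_line`.
#' @return Signed scalar moment arm (mm). A muscle line parallel to the
#'   axis, or one crossing it, gives exactly 0.
#' @examples
#' z <- axis_line(c(0, 0, 0), c(0, 0, 1))
#' scalar_moment_arm(z, muscle_line(c(3, 0, 0), c(3, 5, 0)))  # +3 mm lever
#' @export
scalar_moment_arm <- function(axis, muscle) {
  stopifnot(inherits(axis, "axis_line"), inherits(muscle, "muscle_line"))
  x_hat <- axis$direction
  f_hat <- muscle$direction
  cp <- common_perpendicular(axis, muscle)
  in_plane <- f_hat - sum(f_hat * x_hat) * x_hat
  scale <- sqrt(sum(in_plane^2))          # in [0, 1]
  if (cp$length == 0 || scale == 0) return(0)
  s <- sign(sum(cross3(cp$r_vec, f_hat) * x_hat))
  s * cp$length * scale
}

#' Moment arms about all three axes of a joint frame
#'
#' Applies [scalar_moment_arm()] to the x, y and z axis lines through the
#' origin of an anatomical joint frame. Per the joint-coordinate-system
#' convention, a positive x value is an abduction moment arm, y long-axis
#' rotation, z flexion-extension.
#'
#' @param frame An `anatomical_frame` (in the same space as `muscle`).
#' @param muscle A `muscle_line`.
#' @return Named numeric vector `c(r_x, r_y, r_z)` in mm.
#' @export
mma_triple <- function(frame, muscle) {
  stopifnot(inherits(frame, "anatomical_frame"))
  r <- vapply(1:3, function(k) {
    scalar_moment_arm(axis_line(frame$origin, frame$R[, k]), muscle)
  }, numeric(1))
  names(r) <- c("r_x", "r_y", "r_z")
  r
}

#' Root-mean-square error between two series
#'
#' @param a,b Numeric vectors of equal length.
#' @return `sqrt(mean((a - b)^2))`, in the units of the inputs.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) {
    stop("series lengths differ (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  sqrt(mean((a - b)^2))
}

#' Jointly normalise paired moment-arm series
#'
#' Scales an experimental and a model series for the same muscle by their
#' joint maximum absolute value, so both lie in \[-1, 1\] and signs are
#' preserved; used when plotting paired estimates on a common colour scale.
#'
#' @param experimental,model Numeric vectors (any lengths).
#' @return List with `experimental`, `model` (scaled) and `max_abs`, the
#'   joint normaliser.
#' @export
normalise_mma <- function(experimental, model) {
  m <- max(abs(c(experimental, model)))
  if (!is.finite(m) || m == 0) {
    stop("cannot normalise: all values are zero", call. = FALSE)
  }
  list(experimental = experimental / m, model = model / m, max_abs = m)
}
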