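#' Rigid-body transform
#'
#' A proper rigid-body transform: a 3x3 rotation matrix (orthonormal,
#' determinant +1) plus a 3-vector translation in mm. The transform maps a
#' point `p` expressed in the local frame to world coordinates as
#' `R %*% p + t`.
#'
#' @param rotation 3x3 orthonormal rotation matrix with determinant +1.
#' @param translation Numeric 3-vector (mm). Defaults to zero.
#' @param tol Orthonormality tolerance (default `1e-9`).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' T1 <- rigid_transform(rot_about("z", 90), c(1, 0, 0))
#' transform_points(T1, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0), tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  check_rotation(rotation, tol = tol)
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

check_rotation <- function(R, tol = 1e-9) {
  err <- max(abs(crossprod(R) - diag(3)))
  if (err > sqrt(tol)) {
    stop("rotation matrix is not orthonormal (max |R'R - I| = ",
         format(err), ")", call. = FALSE)
  }
  if (abs(det(R) - 1) > sqrt(tol)) {
    stop("rotation matrix has determinant ", format(det(R)),
         "; a proper rotation (det +1) is required", call. = FALSE)
  }
  invisible(R)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid-body transform\n")
  m <- cbind(x$R, x$t)
  dimnames(m) <- list(c("x", "y", "z"), c("R.x", "R.y", "R.z", "t (mm)"))
  print(round(m, 6))
  invisible(x)
}

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
identity_transform <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Compose two rigid transforms
#'
#' `compose(a, b)` applies `b` first, then `a`: the result maps `p` to
#' `a(b(p))`. Composition is associative and keeps the rotation orthonormal.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param x A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  rigid_transform(t(x$R), as.numeric(-t(x$R) %*% x$t))
}

#' @export
as.matrix.rigid_transform <- function(x, ...) {
  rbind(cbind(x$R, x$t), c(0, 0, 0, 1))
}

#' Apply a rigid transform to points
#'
#' @param x A `rigid_transform`.
#' @param pts Numeric 3-vector or n x 3 matrix of points (mm).
#' @return Points of the same shape, transformed.
#' @export
transform_points <- function(x, pts) {
  stopifnot(inherits(x, "rigid_transform"))
  if (is.null(dim(pts))) {
    return(as.numeric(x$R %*% pts + x$t))
  }
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3L)
  sweep(pts %*% t(x$R), 2L, x$t, "+")
}

#' Elementary rotation matrix
#'
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param angle_deg Rotation angle in degrees (right-hand rule).
#' @return A 3x3 rotation matrix.
#' @export
rot_about <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Rotation matrix from intrinsic Euler angles
#'
#' Intrinsic (body-fixed) rotations applied in the order given, e.g. the
#' default `"xyz"` means: rotate about x, then about the new y, then about
#' the new z, i.e. `R = Rx %*% Ry %*% Rz`.
#'
#' @param angles_deg Numeric 3-vector of angles in degrees, in the order of
#'   `order`.
#' @param order Three-letter Euler order; one of the six Tait-Bryan
#'   permutations of `"x"`, `"y"`, `"z"`.
#' @return A 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(angles_deg, order = "xyz") {
  order <- check_euler_order(order)
  ax <- strsplit(order, "")[[1]]
  rot_about(ax[1], angles_deg[1]) %*%
    rot_about(ax[2], angles_deg[2]) %*%
    rot_about(ax[3], angles_deg[3])
}

check_euler_order <- function(order) {
  order <- tolower(order)
  if (!order %in% c("xyz", "xzy", "yxz", "yzx", "zxy", "zyx")) {
    stop("unsupported Euler order '", order,
         "'; use one of xyz, xzy, yxz, yzx, zxy, zyx", call. = FALSE)
  }
  order
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()] for the six Tait-Bryan orders. Near gimbal
#' lock (middle angle within ~1e-6 degrees of +-90) the first and third
#' rotations become coupled; the decomposition is then made deterministic by
#' setting the third angle to 0 and the result is flagged.
#'
#' @param R 3x3 rotation matrix.
#' @param order Euler order as in [euler_to_matrix()].
#' @return Numeric 3-vector of angles in degrees (attribute `gimbal_lock`
#'   set `TRUE` when the degenerate branch was taken). Angles lie in
#'   (-180, 180].
#' @export
matrix_to_euler <- function(R, order = "xyz") {
  order <- check_euler_order(order)
  check_rotation(R)
  ax <- strsplit(order, "")[[1]]
  i <- match(ax[1], c("x", "y", "z"))
  j <- match(ax[2], c("x", "y", "z"))
  k <- match(ax[3], c("x", "y", "z"))
  # cyclic orders (xyz, yzx, zxy) have parity +1; anti-cyclic -1
  cyc <- (j - i) %% 3 == 1
  s <- if (cyc) 1 else -1
  # For intrinsic i-j-k: R[i,k] = s * sin(beta)
  sb <- s * R[i, k]
  sb <- max(-1, min(1, sb))
  lock_tol <- 1e-6 * pi / 180  # radians off +-pi/2
  if (1 - abs(sb) < 1 - cos(lock_tol)) {
    # gimbal lock: only alpha +- gamma is determined; fix gamma = 0 and
    # recover alpha from the residual rotation R %*% t(Rj(beta))
    beta_deg <- if (sb > 0) 90 else -90
    M <- R %*% t(rot_about(ax[2], beta_deg))
    u <- mod3(i); v <- mod3(u)
    alpha <- atan2(M[v, u], M[u, u])
    ang <- wrap_deg(c(alpha * 180 / pi, beta_deg, 0))
    attr(ang, "gimbal_lock") <- TRUE
    return(ang)
  }
  beta <- asin(sb)
  alpha <- atan2(-s * R[j, k], R[k, k])
  gamma <- atan2(-s * R[i, j], R[i, i])
  ang <- wrap_deg(c(alpha, beta, gamma) * 180 / pi)
  attr(ang, "gimbal_lock") <- FALSE
  ang
}

mod3 <- function(i) (i %% 3L) + 1L

wrap_deg <- function(a) {
  a <- ((a + 180) %% 360) - 180
  a[a == -180] <- 180
  a
}

#' Anatomical coordinate frame on a bone
#'
#' An origin plus a right-handed orthonormal axis triad, expressed in world
#' (or parent-bone) coordinates. By the joint-coordinate-system convention
#' used throughout the package, x is abduction-adduction, y long-axis
#' rotation and z flexion-extension.
#'
#' @param origin 3-point (mm).
#' @param rotation Either a 3x3 matrix whose columns are the x, y, z axes,
#'   or `NULL` to build from `x_axis`/`y_axis`.
#' @param x_axis,y_axis Optional unit axes; z is completed as x cross y.
#' @param bone_id Optional label.
#' @return An object of class `anatomical_frame` with elements `origin`,
#'   `R` (columns are axes) and `bone_id`.
#' @export
anatomical_frame <- function(origin = c(0, 0, 0), rotation = NULL,
                             x_axis = NULL, y_axis = NULL, bone_id = NULL) {
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  if (is.null(rotation)) {
    if (is.null(x_axis) || is.null(y_axis)) {
      rotation <- diag(3)
    } else {
      x <- unitize(x_axis)
      y <- unitize(y_axis - sum(y_axis * x) * x)
      rotation <- cbind(x, y, cross3(x, y))
    }
  }
  check_rotation(rotation)
  structure(list(origin = origin, R = rotation, bone_id = bone_id),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("Anatomical frame", if (!is.null(x$bone_id)) paste0("[", x$bone_id, "]"),
      "\n  origin (mm):", paste(round(x$origin, 4), collapse = ", "), "\n")
  ax <- t(x$R); dimnames(ax) <- list(c("x", "y", "z"), NULL)
  print(round(ax, 6))
  invisible(x)
}

#' Move an anatomical frame with its bone
#'
#' Expresses a frame that is fixed in a bone's local coordinates in world
#' space, given the bone's current transform.
#'
#' @param frame An `anatomical_frame` in bone-local coordinates.
#' @param transform The bone's `rigid_transform` (local to world).
#' @return The frame in world coordinates.
#' @export
move_frame <- function(frame, transform) {
  stopifnot(inherits(frame, "anatomical_frame"),
            inherits(transform, "rigid_transform"))
  anatomical_frame(transform_points(transform, frame$origin),
                   transform$R %*% frame$R, bone_id = frame$bone_id)
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Joint pose of a distal frame relative to a proximal frame
#'
#' Expresses the distal anatomical frame in the proximal frame and
#' decomposes the relative rotation into intrinsic Euler angles (degrees)
#' and the relative origin into translations (mm) along the proximal axes.
#' This is the joint-coordinate-system pose exported per frame of a
#' kinematic trial.
#'
#' @param proximal,distal `anatomical_frame`s in a common (world) space.
#' @param euler_order Euler order (see [euler_to_matrix()]); default
#'   intrinsic `"xyz"` to match common animation-package rotate orders.
#' @return An object of class `joint_pose`: named numeric vector
#'   `rx, ry, rz` (deg) and `tx, ty, tz` (mm) with attributes `euler_order`
#'   and `gimbal_lock`.
#' @export
relative_pose <- function(proximal, distal, euler_order = "xyz") {
  stopifnot(inherits(proximal, "anatomical_frame"),
            inherits(distal, "anatomical_frame"))
  R_rel <- t(proximal$R) %*% distal$R
  t_rel <- as.numeric(t(proximal$R) %*% (distal$origin - proximal$origin))
  ang <- matrix_to_euler(R_rel, euler_order)
  pose <- c(rx = ang[1], ry = ang[2], rz = ang[3],
            tx = t_rel[1], ty = t_rel[2], tz = t_rel[3])
  structure(pose, euler_order = euler_order,
            gimbal_lock = attr(ang, "gimbal_lock"), class = "joint_pose")
}

#' @export
print.joint_pose <- function(x, ...) {
  cat("Joint pose (", attr(x, "euler_order"), " intrinsic)\n", sep = "")
  cat(sprintf("  rotations (deg): rx = %.3f, ry = %.3f, rz = %.3f\n",
              x[["rx"]], x[["ry"]], x[["rz"]]))
  cat(sprintf("  translations (mm): tx = %.3f, ty = %.3f, tz = %.3f\n",
              x[["tx"]], x[["ty"]], x[["tz"]]))
  if (isTRUE(attr(x, "gimbal_lock"))) cat("  [gimbal lock: rz fixed at 0]\n")
  invisible(x)
}

#' Rebuild the relative transform encoded by a joint pose
#'
#' Inverse of [relative_pose()]: returns the rigid transform of the distal
#' frame expressed in the proximal frame.
#'
#' @param pose A `joint_pose`.
#' @return A `rigid_transform`.
#' @export
pose_to_transform <- function(pose) {
  stopifnot(inherits(pose, "joint_pose"))
  rigid_transform(
    euler_to_matrix(c(pose[["rx"]], pose[["ry"]], pose[["rz"]]),
                    attr(pose, "euler_order")),
    c(pose[["tx"]], pose[["ty"]], pose[["tz"]]))
}
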