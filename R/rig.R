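#' Synthetic two-bone joint rig
#'
#' A ground-truth generator emulating a marker-based cadaver trial: a fixed
#' proximal bone and a distal bone articulated at a joint of known type,
#' with straight-line muscles attached to each bone and marker triads
#' rigidly following their bones. Every derived quantity (bone transforms,
#' joint poses, moment arms) has an exact value, so the rig serves as an
#' oracle for the full marker-to-moment-arm pipeline.
#'
#' @param joint Joint type: `"revolute"` (single hinge axis), `"ball"`
#'   (three rotations) or `"free"` (three rotations + three translations).
#' @param centre Joint centre (mm) in the shared reference coordinates.
#' @param axes 3x3 matrix; columns are the joint x, y, z axes.
#' @param revolute_axis For a revolute joint, which axis is the hinge
#'   (`"x"`, `"y"` or `"z"`, default `"z"`, flexion-extension).
#' @param bone_marker_offsets List with `proximal` and `distal` k x 3
#'   matrices of marker positions in bone-local coordinates; each set must
#'   contain at least 3 non-collinear markers. Sensible defaults provided.
#' @param muscles Named list; each element is `list(origin =, insertion =)`
#'   with the origin fixed in the proximal bone and the insertion in the
#'   distal bone (reference coordinates, mm).
#' @return An object of class `synthetic_rig`.
#' @export
synthetic_rig <- function(joint = c("revolute", "ball", "free"),
                          centre = c(0, 0, 0), axes = diag(3),
                          revolute_axis = "z",
                          bone_marker_offsets = NULL, muscles = list()) {
  joint <- match.arg(joint)
  check_rotation(axes)
  if (is.null(bone_marker_offsets)) {
    tri <- rbind(c(0, 0, 0), c(25, 0, 0), c(0, 25, 0), c(0, 5, 25))
    bone_marker_offsets <- list(proximal = sweep(tri, 2, c(-40, 0, 0), "+"),
                                distal = sweep(tri, 2, c(40, 0, 0), "+"))
  }
  for (b in c("proximal", "distal")) {
    check_marker_offsets(bone_marker_offsets[[b]], b)
  }
  stopifnot(revolute_axis %in% c("x", "y", "z"))
  structure(list(joint = joint, centre = as.numeric(centre), axes = axes,
                 revolute_axis = revolute_axis,
                 bone_marker_offsets = bone_marker_offsets,
                 muscles = muscles),
            class = "synthetic_rig")
}

check_marker_offsets <- function(m, label = "bone") {
  m <- as.matrix(m)
  if (nrow(m) < 3L) {
    stop(label, " bone needs at least 3 markers", call. = FALSE)
  }
  sv <- svd(scale(m, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop(label, " bone markers are collinear; a collinear marker set ",
         "cannot constrain rotation about its own axis (the classic ",
         "slender-bone implantation failure)", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.synthetic_rig <- function(x, ...) {
  cat("Synthetic two-bone rig:", x$joint, "joint",
      if (x$joint == "revolute") paste0("about ", x$revolute_axis), "\n")
  cat("  centre (mm):", paste(round(x$centre, 3), collapse = ", "), "\n")
  if (length(x$muscles)) {
    cat("  muscles:", paste(names(x$muscles), collapse = ", "), "\n")
  }
  invisible(x)
}

pose_vector <- function(pose) {
  full <- c(rx = 0, ry = 0, rz = 0, tx = 0, ty = 0, tz = 0)
  if (!is.null(pose)) {
    if (is.null(names(pose))) stop("pose must be a named vector")
    bad <- setdiff(names(pose), names(full))
    if (length(bad)) stop("unknown pose coordinate(s): ",
                          paste(bad, collapse = ", "))
    full[names(pose)] <- pose
  }
  full
}

check_pose_dofs <- function(rig, pose) {
  allowed <- switch(rig$joint,
    revolute = paste0("r", rig$revolute_axis),
    ball = c("rx", "ry", "rz"),
    free = c("rx", "ry", "rz", "tx", "ty", "tz"))
  active <- names(pose)[pose != 0]
  bad <- setdiff(active, allowed)
  if (length(bad)) {
    stop("pose moves coordinate(s) ", paste(bad, collapse = ", "),
         " not admitted by a ", rig$joint, " joint", call. = FALSE)
  }
  invisible(pose)
}

#' Distal-bone transform of a rig at a joint pose
#'
#' The rigid transform taking distal-bone reference coordinates to world,
#' for a pose expressed in joint-axis coordinates (intrinsic x-y-z
#' rotations in degrees about the joint axes, translations in mm along
#' them). The proximal bone is fixed at identity.
#'
#' @param rig A [synthetic_rig()].
#' @param pose Named numeric vector with any of `rx, ry, rz, tx, ty, tz`;
#'   coordinates the joint type does not admit must stay zero.
#' @return A `rigid_transform`.
#' @export
rig_distal_transform <- function(rig, pose) {
  stopifnot(inherits(rig, "synthetic_rig"))
  pose <- check_pose_dofs(rig, pose_vector(pose))
  A <- rig$axes
  R_world <- A %*% euler_to_matrix(pose[c("rx", "ry", "rz")], "xyz") %*% t(A)
  t_world <- as.numeric(A %*% pose[c("tx", "ty", "tz")])
  c0 <- rig$centre
  rigid_transform(R_world, c0 + t_world - as.numeric(R_world %*% c0))
}

resolve_path <- function(rig, path) {
  if (is.character(path)) {
    if (!path %in% names(rig$muscles)) {
      stop("rig has no muscle named '", path, "'", call. = FALSE)
    }
    path <- rig$muscles[[path]]
  }
  stopifnot(is.list(path), !is.null(path$origin), !is.null(path$insertion))
  if (isTRUE(all.equal(as.numeric(path$origin),
                       as.numeric(path$insertion)))) {
    stop("muscle origin and insertion coincide", call. = FALSE)
  }
  path
}

#' Musculotendon length at a rig pose
#'
#' Euclidean distance between the world-space origin (fixed in the
#' proximal bone) and insertion (following the distal bone).
#'
#' @param rig A [synthetic_rig()].
#' @param pose Named pose vector as in [rig_distal_transform()].
#' @param path Muscle name in `rig$muscles`, or a
#'   `list(origin =, insertion =)` pair of 3-points.
#' @return Length in mm.
#' @export
muscle_length <- function(rig, pose, path) {
  path <- resolve_path(rig, path)
  Td <- rig_distal_transform(rig, pose)
  ins <- transform_points(Td, as.numeric(path$insertion))
  sqrt(sum((ins - as.numeric(path$origin))^2))
}

#' Moment arm by tendon travel
#'
#' The tendon-travel (partial-velocity-equivalent) estimator: the negative
#' derivative of musculotendon length with respect to a single rotational
#' joint coordinate, evaluated by central differences,
#' `-(L(theta + h) - L(theta - h)) / (2 h)` with `h` in radians. The
#' resulting sign follows the muscle-action convention: a muscle that
#' shortens as the coordinate increases has a positive moment arm. This
#' equals the geometric moment arm of [scalar_moment_arm()] computed with
#' the muscle line oriented in the direction the force pulls on the distal
#' segment (insertion towards origin); with the line oriented
#' origin-to-insertion the geometric value has the opposite sign.
#'
#' @inheritParams muscle_length
#' @param dof One of `"rx"`, `"ry"`, `"rz"`.
#' @param angle Joint angle (degrees) at which to evaluate.
#' @param step Half-width of the central difference in degrees
#'   (default 0.01; must be at least 1e-6 to stay above floating-point
#'   cancellation).
#' @param base_pose Optional named pose vector for the other coordinates.
#' @return Moment arm in mm (truncation error O(step^2)).
#' @export
tendon_travel_mma <- function(rig, path, dof = "rz", angle = 0, step = 0.01,
                              base_pose = NULL) {
  stopifnot(dof %in% c("rx", "ry", "rz"))
  if (step < 1e-6) {
    stop("step ", step, " deg is below the 1e-6 deg floor; central ",
         "differences lose all precision there", call. = FALSE)
  }
  base <- pose_vector(base_pose)
  up <- base; up[dof] <- angle + step
  dn <- base; dn[dof] <- angle - step
  h <- step * pi / 180
  -(muscle_length(rig, up, path) - muscle_length(rig, dn, path)) / (2 * h)
}

#' Closed-form hinge moment arm
#'
#' Law-of-cosines reference solution for a planar hinge: origin at distance
#' `c_off` from the joint centre in the plane of motion, insertion at
#' radius `a_rad` on the distal segment, both in the plane perpendicular
#' to the hinge axis, with the two attachment position vectors separated
#' by `theta_deg`. Musculotendon length is
#' `L = sqrt(a^2 + c^2 - 2 a c cos(theta))` and the muscle-action moment
#' arm is `-dL/dtheta = -a c sin(theta) / L`.
#'
#' @param a_rad Insertion radius (mm).
#' @param c_off Origin offset (mm).
#' @param theta_deg Joint angle (degrees).
#' @return Moment arm in mm (muscle-action sign convention).
#' @export
hinge_moment_arm <- function(a_rad, c_off, theta_deg) {
  th <- theta_deg * pi / 180
  L <- sqrt(a_rad^2 + c_off^2 - 2 * a_rad * c_off * cos(th))
  if (any(L < 1e-12)) stop("attachments coincide at this angle")
  -(a_rad * c_off * sin(th)) / L
}

#' Motion program for a rig
#'
#' A frame-by-frame schedule of joint coordinates, e.g. cycles of
#' flexion-extension at various abducted and rotated positions.
#'
#' @param poses Data frame with columns among `rx, ry, rz, tx, ty, tz`
#'   (degrees / mm), one row per frame.
#' @param frame_rate Hz (default 60).
#' @return An object of class `motion_program`.
#' @export
motion_program <- function(poses, frame_rate = 60) {
  poses <- as.data.frame(poses)
  bad <- setdiff(names(poses), c("rx", "ry", "rz", "tx", "ty", "tz"))
  if (length(bad)) stop("unknown pose column(s): ", paste(bad, collapse = ", "))
  if (!nrow(poses)) stop("a motion program needs at least one frame")
  stopifnot(frame_rate > 0)
  structure(list(poses = poses, frame_rate = frame_rate),
            class = "motion_program")
}

#' Single-coordinate sweep program
#'
#' @param dof Coordinate to sweep.
#' @param from,to Sweep limits (deg or mm).
#' @param n_frames Number of frames.
#' @param frame_rate Hz.
#' @param base_pose Optional constant values for other coordinates.
#' @return A [motion_program()].
#' @export
sweep_program <- function(dof, from, to, n_frames = 60, frame_rate = 60,
                          base_pose = NULL) {
  base <- pose_vector(base_pose)
  poses <- as.data.frame(as.list(base))[rep(1L, n_frames), , drop = FALSE]
  poses[[dof]] <- seq(from, to, length.out = n_frames)
  rownames(poses) <- NULL
  motion_program(poses, frame_rate)
}

#' Simulate a marker-based trial on a rig
#'
#' Drives the rig through a motion program and returns what a tracking
#' system would see — bone and muscle marker trajectories, optionally with
#' iid isotropic Gaussian noise per coordinate — together with the exact
#' ground truth: true bone transforms, the programmed joint poses and the
#' true per-frame moment arm of every rig muscle about each joint axis.
#'
#' @param rig A [synthetic_rig()].
#' @param program A [motion_program()].
#' @param noise_sd Marker noise standard deviation (mm) per coordinate;
#'   0 for noise-free.
#' @param seed Integer seed; recorded in the trial metadata so a trial can
#'   be regenerated bit-identically.
#' @return A [kin_trial()] whose muscle markers are named
#'   `<muscle>_prox` / `<muscle>_dist`, with an extra element `truth`
#'   (list: `transforms`, `poses`, `mma` — a list of per-muscle n x 3
#'   matrices) and `meta` recording `seed` and `noise_sd`.
#' @export
simulate_trial <- function(rig, program, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(rig, "synthetic_rig"), inherits(program, "motion_program"),
            noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  poses <- program$poses
  n <- nrow(poses)
  T_dist <- lapply(seq_len(n), function(f) {
    rig_distal_transform(rig, unlist(poses[f, , drop = FALSE]))
  })
  T_prox <- rep(list(identity_transform()), n)

  observe <- function(world) {  # world: n x 3
    if (noise_sd > 0) world + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
    else world
  }
  bone_obs <- list()
  for (b in c("proximal", "distal")) {
    offs <- as.matrix(rig$bone_marker_offsets[[b]])
    Ts <- if (b == "proximal") T_prox else T_dist
    arr <- array(NA_real_, c(n, nrow(offs), 3))
    for (k in seq_len(nrow(offs))) {
      world <- t(vapply(seq_len(n), function(f) {
        transform_points(Ts[[f]], offs[k, ])
      }, numeric(3)))
      arr[, k, ] <- observe(world)
    }
    bone_obs[[b]] <- list(offsets = offs, observed = arr)
  }

  ref_frame <- anatomical_frame(rig$centre, rig$axes)
  markers <- list()
  truth_mma <- list()
  for (mn in names(rig$muscles)) {
    path <- resolve_path(rig, mn)
    orig_world <- matrix(rep(as.numeric(path$origin), each = n), n, 3)
    ins_world <- t(vapply(seq_len(n), function(f) {
      transform_points(T_dist[[f]], as.numeric(path$insertion))
    }, numeric(3)))
    markers[[paste0(mn, "_prox")]] <- observe(orig_world)
    markers[[paste0(mn, "_dist")]] <- observe(ins_world)
    truth_mma[[mn]] <- t(vapply(seq_len(n), function(f) {
      mma_triple(ref_frame, muscle_line(orig_world[f, ], ins_world[f, ]))
    }, numeric(3)))
  }

  trial <- kin_trial(frame_rate = program$frame_rate,
                     markers = if (length(markers)) markers else NULL,
                     bone_markers = bone_obs,
                     meta = list(seed = seed, noise_sd = noise_sd))
  trial$truth <- list(transforms = list(proximal = T_prox, distal = T_dist),
                      poses = poses, mma = truth_mma)
  trial
}

#' Least-squares rigid-body fit of marker sets
#'
#' Orthogonal Procrustes (Kabsch) fit of the rigid transform taking
#' bone-local marker offsets onto their observed world positions, one fit
#' per frame, with the determinant constrained to +1 so a reflection is
#' never returned.
#'
#' @param offsets k x 3 matrix of marker positions in bone-local
#'   coordinates (k >= 3, non-collinear).
#' @param observed k x 3 matrix for a single frame, or an n x k x 3 array.
#' @return A `rigid_transform` (single frame) or a list of them.
#' @export
fit_rigid_body <- function(offsets, observed) {
  offsets <- check_marker_offsets(offsets, "this")
  if (is.matrix(observed)) {
    return(kabsch(offsets, observed))
  }
  stopifnot(length(dim(observed)) == 3L)
  lapply(seq_len(dim(observed)[1]), function(f) {
    kabsch(offsets, observed[f, , ])
  })
}

kabsch <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y))
  xm <- colMeans(X); ym <- colMeans(Y)
  H <- crossprod(sweep(X, 2, xm), sweep(Y, 2, ym))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, ym - as.numeric(R %*% xm), tol = 1e-6)
}

#' Point clouds with known envelope volume
#'
#' Uniform samples inside a solid of analytically known volume, for
#' validating alpha-shape envelope volumes: a cube, an L-solid (cube minus
#' one quadrant prism, a genuinely concave shape) or an ellipsoid.
#'
#' @param shape `"cube"`, `"L"` or `"ellipsoid"`.
#' @param n Number of interior samples (>= 100).
#' @param seed Integer seed.
#' @param side Cube / L-solid side length (default 50, in degrees when used
#'   as a pose cloud).
#' @param semi_axes Ellipsoid semi-axes (default `c(30, 20, 10)`).
#' @param include_vertices Append the exact corner vertices (cube and L
#'   only, default `TRUE`) so the convex extent is pinned.
#' @return List with `cloud` (a [pose_cloud()]), `true_volume` and `shape`.
#' @export
make_known_envelope_cloud <- function(shape = c("cube", "L", "ellipsoid"),
                                      n = 1000, seed = 1, side = 50,
                                      semi_axes = c(30, 20, 10),
                                      include_vertices = TRUE) {
  shape <- match.arg(shape)
  stopifnot(n >= 100)
  set.seed(seed)
  s <- side
  if (shape == "cube") {
    pts <- matrix(stats::runif(3 * n, 0, s), n, 3)
    if (include_vertices) {
      pts <- rbind(pts, as.matrix(expand.grid(c(0, s), c(0, s), c(0, s))))
    }
    vol <- s^3
  } else if (shape == "L") {
    pts <- matrix(NA_real_, 0, 3)
    while (nrow(pts) < n) {
      cand <- matrix(stats::runif(3 * n, 0, s), n, 3)
      keep <- !(cand[, 1] > s / 2 & cand[, 2] > s / 2)
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts <- pts[seq_len(n), , drop = FALSE]
    if (include_vertices) {
      xy <- rbind(c(0, 0), c(s, 0), c(s, s / 2), c(s / 2, s / 2),
                  c(s / 2, s), c(0, s))
      corners <- cbind(xy[rep(1:6, 2), ], rep(c(0, s), each = 6))
      pts <- rbind(pts, corners)
    }
    vol <- 0.75 * s^3
  } else {
    a <- semi_axes
    pts <- matrix(NA_real_, 0, 3)
    while (nrow(pts) < n) {
      cand <- matrix(stats::runif(3 * n, -1, 1), n, 3)
      keep <- rowSums(cand^2) <= 1
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts <- sweep(pts[seq_len(n), , drop = FALSE], 2, a, "*")
    vol <- 4 / 3 * pi * prod(a)
  }
  colnames(pts) <- c("rx", "ry", "rz")
  list(cloud = pose_cloud(pts), true_volume = vol, shape = shape)
}
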