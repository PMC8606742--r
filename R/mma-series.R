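#' Kinematic trial container
#'
#' Holds the per-frame data of one marker-based manipulation trial: rigid
#' transforms per bone (if already computed), observed bone-marker
#' positions (from which transforms can be fitted), and point-marker
#' trajectories such as implanted muscle-belly markers.
#'
#' @param frame_rate Sampling rate in Hz (the emulated trials use 60).
#' @param transforms Named list, one entry per bone, each a list of
#'   `rigid_transform`s (one per frame); may be `NULL` if `bone_markers`
#'   are supplied.
#' @param markers Named list of n x 3 matrices (mm), one per point marker
#'   (e.g. proximal/distal muscle-belly markers).
#' @param bone_markers Named list, one entry per bone, each a list with
#'   `offsets` (k x 3 marker positions in bone-local coordinates, k >= 3
#'   non-collinear) and `observed` (n x k x 3 array of world positions).
#' @param meta Optional list of trial metadata (seed, noise level, ...).
#' @return An object of class `kin_trial`.
#' @export
kin_trial <- function(frame_rate = 60, transforms = NULL, markers = NULL,
                      bone_markers = NULL, meta = list()) {
  stopifnot(frame_rate > 0)
  n <- NULL
  if (!is.null(transforms)) n <- length(transforms[[1]])
  if (!is.null(markers)) {
    nm <- unique(vapply(markers, nrow, integer(1)))
    if (length(nm) != 1L) stop("marker series have unequal lengths")
    if (is.null(n)) n <- nm else if (n != nm) {
      stop("marker and transform series have unequal lengths")
    }
  }
  if (!is.null(bone_markers)) {
    nb <- unique(vapply(bone_markers, function(b) dim(b$observed)[1],
                        integer(1)))
    if (length(nb) != 1L) stop("bone-marker series have unequal lengths")
    if (is.null(n)) n <- nb else if (n != nb) {
      stop("bone-marker series length disagrees with other series")
    }
  }
  if (is.null(n)) stop("a trial needs transforms, markers or bone markers")
  structure(list(frame_rate = frame_rate, n_frames = n,
                 transforms = transforms, markers = markers,
                 bone_markers = bone_markers, meta = meta),
            class = "kin_trial")
}

#' @export
print.kin_trial <- function(x, ...) {
  cat("Kinematic trial:", x$n_frames, "frames at", x$frame_rate, "Hz\n")
  if (!is.null(x$transforms)) {
    cat("  bones with transforms:", paste(names(x$transforms), collapse = ", "),
        "\n")
  }
  if (!is.null(x$bone_markers)) {
    cat("  bones with markers:",
        paste(names(x$bone_markers), collapse = ", "), "\n")
  }
  if (!is.null(x$markers)) {
    cat("  point markers:", paste(names(x$markers), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Joint definition
#'
#' Names the proximal and distal bones of a joint and places the joint
#' coordinate system (centre + axis triad) in bone-local coordinates of the
#' reference pose. The same local frame is attached to both bones; the axes
#' about which moment arms are measured follow the proximal bone by
#' default (they are fixed anatomical frames on bones), configurably the
#' distal one.
#'
#' @param proximal,distal Bone names (must match the trial's bones).
#' @param centre Joint centre, bone-local reference coordinates (mm).
#' @param axes 3x3 matrix, columns = x, y, z joint axes in the same
#'   coordinates (default identity).
#' @param euler_order Euler order for pose decomposition (default "xyz").
#' @param axes_from `"proximal"` (default) or `"distal"`: whose animated
#'   copy of the joint frame provides the world-space axes for moment arms.
#' @return An object of class `joint_definition`.
#' @export
joint_definition <- function(proximal, distal, centre = c(0, 0, 0),
                             axes = diag(3), euler_order = "xyz",
                             axes_from = c("proximal", "distal")) {
  axes_from <- match.arg(axes_from)
  frame <- anatomical_frame(centre, axes)
  structure(list(proximal = proximal, distal = distal, frame = frame,
                 euler_order = check_euler_order(euler_order),
                 axes_from = axes_from),
            class = "joint_definition")
}

bone_transforms <- function(trial, bone) {
  if (!is.null(trial$transforms) && bone %in% names(trial$transforms)) {
    return(trial$transforms[[bone]])
  }
  if (!is.null(trial$bone_markers) && bone %in% names(trial$bone_markers)) {
    bm <- trial$bone_markers[[bone]]
    return(fit_rigid_body(bm$offsets, bm$observed))
  }
  stop("trial has neither transforms nor markers for bone '", bone, "'",
       call. = FALSE)
}

#' Per-frame joint pose and muscle moment arms for a trial
#'
#' The core pipeline: obtains each bone's rigid transform per frame
#' (fitting them from bone markers by orthogonal Procrustes when needed),
#' expresses the animated joint frames, decomposes the joint pose, forms
#' the straight muscle line between the two named muscle markers, and
#' computes the signed moment arm about each joint axis at every frame.
#'
#' @param trial A [kin_trial()].
#' @param joint A [joint_definition()].
#' @param muscle Character vector of length 2: names of the proximal and
#'   distal muscle markers in `trial$markers` (order defines the force
#'   direction).
#' @return A data frame of class `mma_series` with columns `frame`, the
#'   pose (`rx`, `ry`, `rz` deg; `tx`, `ty`, `tz` mm) and the moment arms
#'   (`r_x`, `r_y`, `r_z` mm). Attributes record the joint and muscle.
#' @export
mma_time_series <- function(trial, joint, muscle) {
  stopifnot(inherits(trial, "kin_trial"), inherits(joint, "joint_definition"),
            length(muscle) == 2L)
  missing_m <- setdiff(muscle, names(trial$markers))
  if (length(missing_m)) {
    stop("muscle marker(s) not in trial: ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  }
  mp <- trial$markers[[muscle[1]]]
  md <- trial$markers[[muscle[2]]]
  bad <- which(!stats::complete.cases(mp) | !stats::complete.cases(md))
  if (length(bad)) {
    stop("muscle markers missing at frame(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ...", call. = FALSE)
  }
  T_prox <- bone_transforms(trial, joint$proximal)
  T_dist <- bone_transforms(trial, joint$distal)
  n <- trial$n_frames
  out <- matrix(NA_real_, n, 9,
                dimnames = list(NULL, c("rx", "ry", "rz", "tx", "ty", "tz",
                                        "r_x", "r_y", "r_z")))
  for (f in seq_len(n)) {
    fp <- move_frame(joint$frame, T_prox[[f]])
    fd <- move_frame(joint$frame, T_dist[[f]])
    pose <- relative_pose(fp, fd, joint$euler_order)
    axes_frame <- if (joint$axes_from == "proximal") fp else fd
    ml <- muscle_line(mp[f, ], md[f, ])
    out[f, ] <- c(unclass(pose), mma_triple(axes_frame, ml))
  }
  res <- data.frame(frame = seq_len(n), out)
  attr(res, "joint") <- joint
  attr(res, "muscle") <- muscle
  attr(res, "frame_rate") <- trial$frame_rate
  class(res) <- c("mma_series", "data.frame")
  res
}

#' @export
print.mma_series <- function(x, ...) {
  j <- attr(x, "joint"); m <- attr(x, "muscle")
  cat("Moment-arm series: muscle ", paste(m, collapse = " -> "),
      " at joint ", j$proximal, "-", j$distal, ", ", nrow(x), " frames\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4,
                   row.names = FALSE)
  if (nrow(x) > 6) cat("  ... (", nrow(x) - 6, " more frames)\n", sep = "")
  invisible(x)
}

#' @export
summary.mma_series <- function(object, ...) {
  cols <- c("r_x", "r_y", "r_z")
  s <- t(vapply(cols, function(cn) {
    v <- object[[cn]]
    c(min = min(v), median = stats::median(v), max = max(v),
      peak_abs = max(abs(v)))
  }, numeric(4)))
  structure(list(joint = attr(object, "joint"),
                 muscle = attr(object, "muscle"), table = s),
            class = "summary.mma_series")
}

#' @export
print.summary.mma_series <- function(x, ...) {
  cat("Moment arms (mm) for muscle", paste(x$muscle, collapse = " -> "),
      "at joint", paste(x$joint$proximal, x$joint$distal, sep = "-"), "\n")
  print(round(x$table, 3))
  invisible(x)
}

#' @export
plot.mma_series <- function(x, which = c("r_x", "r_y", "r_z"), ...) {
  t <- (x$frame - 1) / attr(x, "frame_rate")
  cols <- c(r_x = "firebrick", r_y = "forestgreen", r_z = "steelblue")
  graphics::matplot(t, as.matrix(x[, which, drop = FALSE]), type = "l",
                    lty = 1, col = cols[which], xlab = "time (s)",
                    ylab = "moment arm (mm)", ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  graphics::legend("topright", legend = which, col = cols[which], lty = 1,
                   bty = "n")
  invisible(x)
}
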