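#' Per-specimen range records
#'
#' One row per specimen-side per degree of freedom: the minimum and
#' maximum joint coordinate reached across that specimen's trials.
#'
#' @param specimen,side,joint,dof Character vectors (recycled as needed).
#' @param min,max Numeric extremes (degrees for rotations, mm for
#'   translations); `min <= max` row-wise.
#' @return A data frame of class `range_records`.
#' @export
range_records <- function(specimen, side, joint, dof, min, max) {
  d <- data.frame(specimen = specimen, side = side, joint = joint,
                  dof = dof, min = as.numeric(min), max = as.numeric(max))
  if (any(d$min > d$max)) stop("range records with min > max", call. = FALSE)
  class(d) <- c("range_records", "data.frame")
  d
}

#' Pool per-specimen ranges for one degree of freedom
#'
#' The pooled range across animals: the smallest minimum and largest
#' maximum over all specimen-sides (the largest joint angle for each motion
#' taken across animals), and the total possible excursion `max - min`.
#'
#' @param records A [range_records()] data frame (or compatible) holding a
#'   single `dof`.
#' @return Named numeric vector `c(min, max, total)`.
#' @export
pooled_range <- function(records) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("no records to pool", call. = FALSE)
  if (length(unique(records$dof)) > 1L) {
    stop("records mix degrees of freedom: ",
         paste(unique(records$dof), collapse = ", "),
         "; pool one dof at a time", call. = FALSE)
  }
  lo <- min(records$min); hi <- max(records$max)
  c(min = lo, max = hi, total = hi - lo)
}

#' Pool every degree of freedom in a set of range records
#'
#' @param records A [range_records()] data frame.
#' @return Data frame with one row per joint-dof: pooled `min`, `max`,
#'   `total`.
#' @export
pooled_range_table <- function(records) {
  records <- as.data.frame(records)
  key <- interaction(records$joint, records$dof, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    p <- pooled_range(g)
    data.frame(joint = g$joint[1], dof = g$dof[1],
               min = p[["min"]], max = p[["max"]], total = p[["total"]])
  }))
  rownames(out) <- NULL
  out[order(match(out$joint, unique(records$joint)),
            match(out$dof, unique(records$dof))), , drop = FALSE]
}

#' Pooled and mean translation totals
#'
#' For a translational degree of freedom: the pooled total (as in
#' [pooled_range()]) plus the arithmetic mean of the per-specimen-side
#' totals `max - min`, the summary quoted for joint-surface translations.
#'
#' @param records A [range_records()] data frame for one joint-axis.
#' @return Named numeric vector `c(pooled_total, mean_total)` in mm.
#' @export
translation_summary <- function(records) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("no records", call. = FALSE)
  p <- pooled_range(records)
  c(pooled_total = p[["total"]], mean_total = mean(records$max - records$min))
}

#' Pose cloud
#'
#' An N x 3 matrix of joint rotations (rx, ry, rz in degrees), one row per
#' frame: the raw material of a pose-space range-of-motion envelope.
#'
#' @param x N x 3 numeric matrix (or data frame) of finite values.
#' @param corrected Logical: has cosine correction been applied already?
#' @return A matrix of class `pose_cloud` with attribute `corrected`.
#' @export
pose_cloud <- function(x, corrected = FALSE) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L)
  if (!all(is.finite(x))) stop("pose cloud contains non-finite values",
                               call. = FALSE)
  colnames(x) <- c("rx", "ry", "rz")
  structure(x, corrected = corrected, class = c("pose_cloud", "matrix",
                                                "array"))
}

#' @export
print.pose_cloud <- function(x, ...) {
  cat("Pose cloud:", nrow(x), "poses",
      if (isTRUE(attr(x, "corrected"))) "(cosine-corrected)", "\n")
  print(round(utils::head(unclass(x), 4), 3))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' Cosine-correct a pose cloud
#'
#' De-distorts Euler pose space by rescaling the coordinate of greatest
#' variation by the cosine of a modulating coordinate:
#' `x' = x * cos(y_rad)`, leaving the other coordinates unchanged. With
#' the default axes the x (abduction-adduction) angle is corrected by the
#' y (long-axis rotation) angle. The correction never increases the
#' corrected coordinate's magnitude and is odd in it.
#'
#' @param cloud A [pose_cloud()] (degrees), not yet corrected.
#' @param corrected_axis Column to correct (default `"rx"`).
#' @param modulating_axis Column whose cosine modulates (default `"ry"`).
#' @return A corrected [pose_cloud()].
#' @export
cosine_correct <- function(cloud, corrected_axis = "rx",
                           modulating_axis = "ry") {
  stopifnot(inherits(cloud, "pose_cloud"))
  if (isTRUE(attr(cloud, "corrected"))) {
    stop("pose cloud is already cosine-corrected; correcting twice would ",
         "compound the distortion", call. = FALSE)
  }
  stopifnot(corrected_axis %in% colnames(cloud),
            modulating_axis %in% colnames(cloud))
  out <- unclass(cloud)
  out[, corrected_axis] <- out[, corrected_axis] *
    cos(out[, modulating_axis] * pi / 180)
  pose_cloud(out, corrected = TRUE)
}
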