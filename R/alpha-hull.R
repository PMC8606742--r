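#' Alpha-shape range-of-motion envelope
#'
#' Wraps a pose cloud in a concave hull: the 3D Delaunay tetrahedralisation
#' filtered by an alpha criterion, with the envelope volume taken as the
#' sum of retained tetrahedron volumes (cubic degrees for rotational pose
#' clouds). In the default `"radius"` dialect a tetrahedron is retained
#' when its circumsphere radius is at most `alpha` (so alpha is
#' commensurate with the degree-scaled axes); the `"reciprocal"` dialect
#' retains radii at most `1/alpha`. As `alpha` grows the envelope fills in
#' monotonically towards the convex hull.
#'
#' @param cloud A [pose_cloud()] (or N x 3 matrix), N >= 4, not coplanar.
#' @param alpha Positive alpha threshold (degrees in the radius dialect).
#' @param dialect `"radius"` (default) or `"reciprocal"`; recorded in the
#'   result so outputs are self-describing.
#' @return An object of class `rom_envelope`: `points`, `tets` (retained
#'   tetrahedra, vertex indices), `faces` (boundary triangles), `volume`,
#'   `convex_volume` (alpha = Inf volume), `alpha`, `dialect`, and
#'   `delaunay` (the full tetrahedralisation, reusable via
#'   [update_alpha()]).
#' @export
alpha_hull <- function(cloud, alpha = 20, dialect = c("radius", "reciprocal")) {
  dialect <- match.arg(dialect)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  pts <- unclass(as.matrix(cloud))
  if (nrow(pts) < 4L) {
    stop("an envelope needs at least 4 poses", call. = FALSE)
  }
  dt <- delaunay3(pts)
  env <- list(points = dt$points, delaunay = dt, dialect = dialect,
              convex_volume = sum(dt$volumes))
  class(env) <- "rom_envelope"
  update_alpha(env, alpha)
}

#' Re-filter an envelope at a new alpha
#'
#' Reuses the stored Delaunay tetrahedralisation, so sweeping alpha over a
#' fixed cloud is cheap.
#'
#' @param envelope A `rom_envelope`.
#' @param alpha New alpha threshold.
#' @return The updated `rom_envelope`.
#' @export
update_alpha <- function(envelope, alpha) {
  stopifnot(inherits(envelope, "rom_envelope"), alpha > 0)
  dt <- envelope$delaunay
  thr <- if (envelope$dialect == "radius") alpha else 1 / alpha
  keep <- dt$circumradius <= thr
  envelope$tets <- dt$tets[keep, , drop = FALSE]
  envelope$volume <- sum(dt$volumes[keep])
  envelope$alpha <- alpha
  envelope$faces <- boundary_faces(envelope$tets)
  envelope
}

boundary_faces <- function(tets) {
  if (!nrow(tets)) return(matrix(integer(0), 0, 3))
  faces <- rbind(tets[, c(1, 2, 3), drop = FALSE],
                 tets[, c(1, 2, 4), drop = FALSE],
                 tets[, c(1, 3, 4), drop = FALSE],
                 tets[, c(2, 3, 4), drop = FALSE])
  fs <- t(apply(faces, 1L, sort))
  key <- paste(fs[, 1], fs[, 2], fs[, 3])
  faces[!(key %in% key[duplicated(key)]), , drop = FALSE]
}

#' @export
print.rom_envelope <- function(x, ...) {
  cat("ROM envelope (alpha complex)\n")
  cat("  poses:", nrow(x$points), " alpha:", x$alpha,
      paste0("(", x$dialect, " dialect)"), "\n")
  cat("  retained tetrahedra:", nrow(x$tets), "of", nrow(x$delaunay$tets),
      "\n")
  cat(sprintf("  volume: %.1f cubic degrees (convex hull %.1f)\n",
              x$volume, x$convex_volume))
  invisible(x)
}

#' @export
plot.rom_envelope <- function(x, ...) {
  pr <- as.data.frame(x$points)
  graphics::pairs(pr, pch = 16, cex = 0.4,
                  col = grDevices::adjustcolor("steelblue", 0.5),
                  main = sprintf("ROM envelope: %.0f cubic degrees",
                                 x$volume), ...)
  invisible(x)
}

# clip the ray origin + t * dir (t >= 0) against one tetrahedron; returns
# the largest t inside, or -Inf when the ray misses it
ray_tet_max_t <- function(P, origin, dir, tol = 1e-9) {
  tlo <- 0; thi <- Inf
  opp <- c(4L, 3L, 2L, 1L)
  combs <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  for (k in 1:4) {
    v <- P[combs[k, ], , drop = FALSE]
    nrm <- cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    # orient inward (towards the opposite vertex)
    if (sum(nrm * (P[opp[k], ] - v[1, ])) < 0) nrm <- -nrm
    a <- sum(nrm * dir)
    b <- sum(nrm * (origin - v[1, ]))
    # constraint: b + t a >= 0
    if (abs(a) < tol) {
      if (b < -tol) return(-Inf)
    } else if (a > 0) {
      tlo <- max(tlo, -b / a)
    } else {
      thi <- min(thi, -b / a)
    }
  }
  if (tlo <= thi + tol) thi else -Inf
}

point_in_tets <- function(envelope, p, tol = 1e-7) {
  tets <- envelope$tets
  pts <- envelope$points
  for (i in seq_len(nrow(tets))) {
    P <- pts[tets[i, ], , drop = FALSE]
    A <- cbind(P[2, ] - P[1, ], P[3, ] - P[1, ], P[4, ] - P[1, ])
    bc <- tryCatch(solve(A, p - P[1, ]), error = function(e) NULL)
    if (is.null(bc)) next
    if (all(bc >= -tol) && sum(bc) <= 1 + tol) return(TRUE)
  }
  FALSE
}

#' Compare single-axis model ROM limits with an experimental envelope
#'
#' Checks, for each rotational axis and direction, whether the pose a
#' model reaches by a pure single-axis rotation from the reference pose
#' lies inside the experimental envelope, and by how much it overshoots
#' the envelope's extent along that axis.
#'
#' @param envelope A `rom_envelope` in the same joint coordinate system.
#' @param model_limits 3 x 2 matrix (rows rx, ry, rz; columns min, max in
#'   degrees), or a named list of `c(min, max)` pairs.
#' @param reference Reference pose the single-axis rotations start from
#'   (default the origin).
#' @return Data frame with one row per axis-direction: the model `limit`,
#'   the envelope's `extent` along that ray, the `excess` (positive where
#'   the model exceeds the envelope) and `contained` (is the model extreme
#'   inside the envelope?).
#' @export
single_axis_rom_overlay <- function(envelope, model_limits,
                                    reference = c(0, 0, 0)) {
  stopifnot(inherits(envelope, "rom_envelope"))
  if (is.list(model_limits)) {
    model_limits <- do.call(rbind, model_limits[c("rx", "ry", "rz")])
  }
  model_limits <- as.matrix(model_limits)
  stopifnot(identical(dim(model_limits), c(3L, 2L)))
  axes <- diag(3)
  out <- vector("list", 6L)
  k <- 0L
  for (i in 1:3) {
    for (j in 1:2) {
      k <- k + 1L
      lim <- model_limits[i, j]
      dir <- axes[i, ] * (if (j == 1) -1 else 1)
      extent <- 0
      for (ti in seq_len(nrow(envelope$tets))) {
        P <- envelope$points[envelope$tets[ti, ], , drop = FALSE]
        tmax <- ray_tet_max_t(P, reference, dir)
        if (tmax > extent) extent <- tmax
      }
      target <- reference + abs(lim) * dir
      out[[k]] <- data.frame(
        axis = c("rx", "ry", "rz")[i],
        direction = if (j == 1) "min" else "max",
        limit = lim,
        extent = (if (j == 1) -1 else 1) * extent,
        excess = abs(lim) - extent,
        contained = point_in_tets(envelope, target))
    }
  }
  do.call(rbind, out)
}
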