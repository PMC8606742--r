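# 3D Delaunay tetrahedralisation by incremental insertion (Bowyer-Watson).
# Written in-package: the alpha-complex envelope needs Delaunay tetrahedra
# with circumradii, and no installed R package provides 3D Delaunay.
# Intended scale: a few thousand points (pose clouds), pure R, vectorised
# circumsphere tests per insertion.

tet_circumsphere <- function(P) {
  # P: 4 x 3 vertex matrix. Returns list(centre, r2); flat tets get r2 = Inf.
  A <- 2 * (P[2:4, , drop = FALSE] -
              matrix(P[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(P[2:4, , drop = FALSE]^2) - sum(P[1, ]^2)
  ctr <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(ctr) || !all(is.finite(ctr))) {
    return(list(centre = colMeans(P), r2 = Inf))
  }
  list(centre = as.numeric(ctr), r2 = sum((ctr - P[1, ])^2))
}

tet_volume <- function(P) {
  abs(det(rbind(P[2, ] - P[1, ], P[3, ] - P[1, ], P[4, ] - P[1, ]))) / 6
}

# deterministic pseudo-random insertion order (independent of the user RNG)
scramble_order <- function(n) {
  state <- 42L
  key <- numeric(n)
  for (i in seq_len(n)) {
    state <- (1103515245 * state + 12345) %% 2147483648
    key[i] <- state
  }
  order(key)
}

#' 3D Delaunay tetrahedralisation
#'
#' Incremental Bowyer-Watson construction. Exact duplicates are dropped.
#' Returns the tetrahedra with their volumes and circumradii, the raw
#' material of the alpha complex used for range-of-motion envelopes.
#'
#' @param points N x 3 numeric matrix, N >= 4, not all (near-)coplanar.
#' @return List with `points` (the deduplicated input), `tets` (m x 4
#'   vertex-index matrix), `volumes` (mm^3 or cubic degrees) and
#'   `circumradius` (same length).
#' @export
delaunay3 <- function(points) {
  pts0 <- as.matrix(points)
  storage.mode(pts0) <- "double"
  stopifnot(ncol(pts0) == 3L)
  pts0 <- unique(pts0)
  n <- nrow(pts0)
  if (n < 4L) stop("need at least 4 distinct points", call. = FALSE)
  sv <- svd(scale(pts0, scale = FALSE))$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    stop("point cloud is degenerate (coplanar or collinear): a 3D ",
         "tetrahedralisation needs full-rank spread", call. = FALSE)
  }

  ctr <- colMeans(pts0)
  scale_r <- max(sqrt(rowSums(sweep(pts0, 2, ctr)^2)))
  # deterministic symbolic perturbation: breaks exactly cospherical /
  # coplanar ties (e.g. box corners) that stall Bowyer-Watson; volumes are
  # still measured on the unperturbed coordinates, so the error is O(jitter)
  jit <- 1e-8 * scale_r
  state <- 20260923
  jmat <- matrix(0, n, 3)
  for (k in seq_len(3L * n)) {
    state <- (1103515245 * state + 12345) %% 2147483648
    jmat[k] <- (state / 2147483648 - 0.5) * jit
  }
  pts <- pts0 + jmat
  K <- 1e4 * scale_r
  super <- rbind(ctr + K * c(1, 1, 1), ctr + K * c(-1, -1, 1),
                 ctr + K * c(-1, 1, -1), ctr + K * c(1, -1, -1))
  allp <- rbind(pts, super)
  is_super <- function(idx) idx > n

  cap <- max(64L, 8L * n)
  tets <- matrix(NA_integer_, cap, 4)
  ccs <- matrix(NA_real_, cap, 3)
  r2s <- rep(NA_real_, cap)
  alive <- logical(cap)
  m <- 0L

  add_tet <- function(v) {
    if (m + 1L > cap) {  # grow
      cap2 <- 2L * cap
      tets2 <- matrix(NA_integer_, cap2, 4); tets2[1:m, ] <- tets[1:m, ]
      ccs2 <- matrix(NA_real_, cap2, 3); ccs2[1:m, ] <- ccs[1:m, ]
      r2s2 <- rep(NA_real_, cap2); r2s2[1:m] <- r2s[1:m]
      alive2 <- logical(cap2); alive2[1:m] <- alive[1:m]
      tets <<- tets2; ccs <<- ccs2; r2s <<- r2s2; alive <<- alive2
      cap <<- cap2
    }
    m <<- m + 1L
    cs <- tet_circumsphere(allp[v, , drop = FALSE])
    tets[m, ] <<- v
    ccs[m, ] <<- cs$centre
    r2s[m] <<- cs$r2
    alive[m] <<- TRUE
  }
  add_tet(c(n + 1L, n + 2L, n + 3L, n + 4L))

  eps2 <- (1e-9 * scale_r)^2
  fkey_base <- as.numeric(n + 5L)

  for (p_i in scramble_order(n)) {
    p <- pts[p_i, ]
    idx <- which(alive[seq_len(m)])
    d2 <- (ccs[idx, 1] - p[1])^2 + (ccs[idx, 2] - p[2])^2 +
      (ccs[idx, 3] - p[3])^2
    bad <- idx[d2 < r2s[idx] - eps2]
    if (!length(bad)) {
      # point on/outside every circumsphere within tolerance: take the
      # nearest-sphere tet so insertion always proceeds
      bad <- idx[which.min(d2 - r2s[idx])]
    } else if (length(bad) > 1L) {
      # keep only the face-connected component of the deepest-contained
      # tet: a disconnected "bad" set (a roundoff artefact of sliver
      # circumspheres) would punch a non-star cavity and corrupt the mesh
      seed_t <- bad[which.min((d2 - r2s[idx])[match(bad, idx)])]
      bverts <- tets[bad, , drop = FALSE]
      comp <- rep(FALSE, length(bad))
      comp[match(seed_t, bad)] <- TRUE
      repeat {
        inset <- unique(as.vector(bverts[comp, , drop = FALSE]))
        shares <- rowSums(matrix(bverts %in% inset, ncol = 4)) >= 3
        newc <- shares & !comp
        if (!any(newc)) break
        comp <- comp | newc
      }
      bad <- bad[comp]
    }
    # cavity boundary: faces of bad tets occurring exactly once
    bt <- tets[bad, , drop = FALSE]
    faces <- rbind(bt[, c(1, 2, 3), drop = FALSE],
                   bt[, c(1, 2, 4), drop = FALSE],
                   bt[, c(1, 3, 4), drop = FALSE],
                   bt[, c(2, 3, 4), drop = FALSE])
    fs <- t(apply(faces, 1L, sort))
    key <- fs[, 1] + fkey_base * (fs[, 2] + fkey_base * fs[, 3])
    once <- !(key %in% key[duplicated(key)])
    alive[bad] <- FALSE
    for (fi in which(once)) {
      add_tet(c(faces[fi, ], p_i))
    }
    if (m > 4L * max(n, 64L) && sum(alive[seq_len(m)]) < m / 2) {
      keep <- which(alive[seq_len(m)])
      m2 <- length(keep)
      tets[seq_len(m2), ] <- tets[keep, ]; ccs[seq_len(m2), ] <- ccs[keep, ]
      r2s[seq_len(m2)] <- r2s[keep]
      alive[] <- FALSE; alive[seq_len(m2)] <- TRUE
      m <- m2
    }
  }

  keep <- which(alive[seq_len(m)])
  final <- tets[keep, , drop = FALSE]
  real <- rowSums(matrix(is_super(final), ncol = 4)) == 0
  final <- final[real, , drop = FALSE]
  vols <- apply(final, 1L, function(v) tet_volume(pts0[v, , drop = FALSE]))
  rads <- sqrt(r2s[keep][real])
  list(points = pts0, tets = final, volumes = vols, circumradius = rads)
}
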