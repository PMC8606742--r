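test_that("common perpendicular handles orthogonal, intersecting and parallel pairs", {
  cp <- common_perpendicular(axis_line(c(0, 0, 0), c(1, 0, 0)),
                             axis_line(c(0, 0, 5), c(0, 1, 0)))
  expect_equal(cp$r_vec, c(0, 0, 5), tolerance = 1e-12)
  expect_equal(cp$length, 5, tolerance = 1e-12)
  expect_false(cp$degenerate)

  cp2 <- common_perpendicular(axis_line(c(0, 0, 0), c(1, 0, 0)),
                              axis_line(c(3, 0, 0), c(0, 1, 0)))
  expect_lt(cp2$length, 1e-9)

  cp3 <- common_perpendicular(axis_line(c(0, 0, 0), c(1, 0, 0)),
                              axis_line(c(0, 4, 0), c(-1, 0, 0)))
  expect_true(cp3$degenerate)
  expect_equal(cp3$length, 4, tolerance = 1e-12)
})

test_that("common perpendicular length matches a staged grid-search oracle", {
  set.seed(31)
  n_checked <- 0
  while (n_checked < 60) {
    a <- axis_line(rnorm(3, sd = 5), rnorm(3))
    b <- axis_line(rnorm(3, sd = 5), rnorm(3))
    if (sqrt(sum(xprod(a$direction, b$direction)^2)) < 0.1) next  # near-parallel
    n_checked <- n_checked + 1
    cp <- common_perpendicular(a, b)
    # brute-force refinement of min distance over the two line parameters
    dist2 <- function(s, t) {
      w <- outer(s, rep(1, length(t)))
      f <- matrix(0, length(s), length(t))
      for (k in 1:3) {
        d <- outer(a$point[k] + s * a$direction[k],
                   b$point[k] + t * b$direction[k], "-")
        f <- f + d^2
      }
      f
    }
    lo_s <- -80; hi_s <- 80; lo_t <- -80; hi_t <- 80
    for (stage in 1:3) {
      s <- seq(lo_s, hi_s, length.out = 401)
      t <- seq(lo_t, hi_t, length.out = 401)
      f <- dist2(s, t)
      ij <- arrayInd(which.min(f), dim(f))
      hs <- (hi_s - lo_s) / 400; ht <- (hi_t - lo_t) / 400
      lo_s <- s[ij[1]] - 2 * hs; hi_s <- s[ij[1]] + 2 * hs
      lo_t <- t[ij[2]] - 2 * ht; hi_t <- t[ij[2]] + 2 * ht
    }
    expect_equal(cp$length, sqrt(min(f)), tolerance = 1e-3)
  }
})

test_that("the foot points realise the perpendicular segment", {
  set.seed(32)
  for (i in 1:50) {
    a <- axis_line(rnorm(3, sd = 5), rnorm(3))
    b <- axis_line(rnorm(3, sd = 5), rnorm(3))
    cp <- common_perpendicular(a, b)
    expect_equal(sqrt(sum((cp$foot_muscle - cp$foot_axis)^2)), cp$length,
                 tolerance = 1e-9)
    if (!cp$degenerate && cp$length > 1e-6) {
      r_hat <- cp$r_vec / cp$length
      expect_lt(abs(sum(r_hat * a$direction)), 1e-9)
      expect_lt(abs(sum(r_hat * b$direction)), 1e-9)
    }
  }
})

test_that("scalar moment arm: planar lever, axis-parallel muscle, zero-length rejection", {
  z <- axis_line(c(0, 0, 0), c(0, 0, 1))
  expect_equal(scalar_moment_arm(z, muscle_line(c(3, 0, 0), c(3, 5, 0))), 3,
               tolerance = 1e-12)
  expect_equal(scalar_moment_arm(z, muscle_line(c(3, 0, 0), c(3, 0, 4))), 0,
               tolerance = 1e-12)
  expect_error(muscle_line(c(1, 1, 1), c(1, 1, 1)), "coincident")
})

test_that("scalar moment arm equals the torque-per-unit-force oracle on random configurations", {
  set.seed(33)
  worst <- 0
  for (i in 1:500) {
    ax <- axis_line(rnorm(3, sd = 10), rnorm(3))
    p <- rnorm(3, sd = 10)
    ml <- muscle_line(p, p + rnorm(3))
    v <- scalar_moment_arm(ax, ml)
    oracle <- sum(xprod(p - ax$point, ml$direction) * ax$direction)
    worst <- max(worst, abs(v - oracle))
  }
  expect_lt(worst, 1e-9)
})

test_that("scalar moment arm depends only on the muscle's line, not the points chosen on it", {
  set.seed(34)
  for (i in 1:50) {
    ax <- axis_line(rnorm(3, sd = 10), rnorm(3))
    p <- rnorm(3, sd = 10); d <- rnorm(3)
    base <- scalar_moment_arm(ax, muscle_line(p, p + d))
    for (k in 1:4) {
      s <- rnorm(1, sd = 5); len <- runif(1, 0.5, 4)
      shifted <- muscle_line(p + s * d, p + s * d + len * d)
      expect_equal(scalar_moment_arm(ax, shifted), base, tolerance = 1e-8)
    }
    flipped <- muscle_line(p + d, p)
    expect_equal(scalar_moment_arm(ax, flipped), -base, tolerance = 1e-8)
  }
})

test_that("|r_theta| never exceeds the perpendicular distance; equality iff perpendicular force", {
  set.seed(35)
  for (i in 1:100) {
    ax <- axis_line(rnorm(3, sd = 10), rnorm(3))
    p <- rnorm(3, sd = 10)
    ml <- muscle_line(p, p + rnorm(3))
    cp <- common_perpendicular(ax, ml)
    expect_lte(abs(scalar_moment_arm(ax, ml)), cp$length + 1e-9)
  }
  # exactly perpendicular: scaling factor 1
  z <- axis_line(c(0, 0, 0), c(0, 0, 1))
  ml <- muscle_line(c(2, 0, 3), c(2, 7, 3))
  cp <- common_perpendicular(z, ml)
  expect_equal(abs(scalar_moment_arm(z, ml)), cp$length, tolerance = 1e-12)
})

test_that("moment arms are equivariant under a common rigid motion", {
  set.seed(36)
  for (i in 1:40) {
    fr <- rand_frame()
    p <- rnorm(3, sd = 10)
    ml <- muscle_line(p, p + rnorm(3))
    g <- rand_transform()
    r1 <- mma_triple(fr, ml)
    r2 <- mma_triple(move_frame(fr, g),
                     muscle_line(transform_points(g, ml$p_prox),
                                 transform_points(g, ml$p_dist)))
    expect_lt(max(abs(r1 - r2)), 1e-9)
  }
})

test_that("mma_triple matches per-axis calls and shows the planar-lever pattern", {
  fr <- anatomical_frame(c(0, 0, 0))
  expect_lt(max(abs(mma_triple(fr, muscle_line(c(-5, 0, 0), c(5, 0, 0))))),
            1e-12)
  r <- mma_triple(fr, muscle_line(c(3, 0, 0), c(3, 5, 0)))
  expect_equal(unname(r), c(0, 0, 3), tolerance = 1e-12)
  set.seed(37)
  for (i in 1:20) {
    fr <- rand_frame()
    p <- rnorm(3, sd = 10)
    ml <- muscle_line(p, p + rnorm(3))
    r <- mma_triple(fr, ml)
    for (k in 1:3) {
      expect_equal(unname(r[k]),
                   scalar_moment_arm(axis_line(fr$origin, fr$R[, k]), ml),
                   tolerance = 1e-12)
    }
  }
})

test_that("rmse matches the direct formula and rejects length mismatch", {
  expect_identical(rmse(1:5, 1:5), 0)
  expect_equal(rmse(rep(0, 9), rep(2.5, 9)), 2.5)
  set.seed(38)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(rmse(a, b), sqrt(mean((a - b)^2)), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "lengths differ")
})

test_that("joint normalisation maps the largest magnitude to +-1 and is scale-free", {
  out <- normalise_mma(c(-4, 2), c(1, -8))
  expect_equal(out$max_abs, 8)
  expect_equal(min(c(out$experimental, out$model)), -1)
  neg <- normalise_mma(c(-2, -6), c(-1, -3))
  expect_true(all(neg$experimental <= 0))
  set.seed(39)
  a <- rnorm(20); b <- rnorm(20)
  s1 <- normalise_mma(a, b); s2 <- normalise_mma(5.5 * a, 5.5 * b)
  expect_equal(s1$experimental, s2$experimental, tolerance = 1e-12)
  expect_error(normalise_mma(c(0, 0), c(0, 0)), "zero")
})
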