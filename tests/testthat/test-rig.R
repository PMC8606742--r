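hinge_flexor_rig <- function() {
  synthetic_rig("revolute",
                muscles = list(flex = list(origin = c(0, 30, 0),
                                           insertion = c(0, 12, 0))))
}

test_that("trials are reproducible under a seed and change with it", {
  rig <- hinge_flexor_rig()
  prog <- sweep_program("rz", -30, 60, n_frames = 40)
  t1 <- simulate_trial(rig, prog, noise_sd = 0.2, seed = 99)
  t2 <- simulate_trial(rig, prog, noise_sd = 0.2, seed = 99)
  t3 <- simulate_trial(rig, prog, noise_sd = 0.2, seed = 100)
  expect_identical(t1$markers, t2$markers)
  expect_identical(t1$bone_markers, t2$bone_markers)
  expect_false(identical(t1$markers, t3$markers))
  expect_identical(t1$meta$seed, 99)
})

test_that("noise-free marker fits recover the true transforms exactly", {
  rig <- hinge_flexor_rig()
  prog <- sweep_program("rz", -45, 45, n_frames = 25)
  tr <- simulate_trial(rig, prog, noise_sd = 0)
  bm <- tr$bone_markers$distal
  fits <- fit_rigid_body(bm$offsets, bm$observed)
  for (f in c(1, 13, 25)) {
    expect_lt(max(abs(as.matrix(fits[[f]]) -
                        as.matrix(tr$truth$transforms$distal[[f]]))), 1e-9)
  }
})

test_that("collinear marker sets are rejected with the failure mode named", {
  line <- cbind(seq(0, 20, length.out = 4), 0, 0)
  expect_error(fit_rigid_body(line, line), "collinear")
  expect_error(synthetic_rig(bone_marker_offsets = list(proximal = line,
                                                        distal = line)),
               "collinear")
})

test_that("noisy fits keep determinant +1 and calibrated residuals", {
  set.seed(81)
  offsets <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0.5, 10))
  sigma <- 0.3
  dets <- numeric(200)
  resid2 <- numeric(0)
  for (i in 1:200) {
    Tt <- rand_transform()
    obs <- transform_points(Tt, offsets) +
      matrix(rnorm(12, 0, sigma), 4, 3)
    fit <- fit_rigid_body(offsets, obs)
    dets[i] <- det(fit$R)
    resid2 <- c(resid2, as.numeric(obs - transform_points(fit, offsets))^2)
  }
  expect_true(all(abs(dets - 1) < 1e-9))
  # 12 observations minus 6 rigid dof: residual RMS ~ sigma * sqrt(1/2)
  rms <- sqrt(mean(resid2))
  expect_gt(rms, 0.4 * sigma)
  expect_lt(rms, 1.1 * sigma)
  # near-degenerate noisy frames (flat triads) still never give reflections
  flat <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(5, 5, 0.01))
  for (i in 1:50) {
    obs <- transform_points(rand_transform(), flat) +
      matrix(rnorm(12, 0, 0.5), 4, 3)
    expect_gt(det(fit_rigid_body(flat, obs)$R), 0)
  }
})

test_that("the full pipeline recovers programmed poses and closed-form moment arms", {
  rig <- hinge_flexor_rig()
  prog <- sweep_program("rz", -60, 60, n_frames = 120)
  tr <- simulate_trial(rig, prog, noise_sd = 0)
  jd <- joint_definition("proximal", "distal")
  ms <- mma_time_series(tr, jd, c("flex_prox", "flex_dist"))
  expect_lt(max(abs(ms$rz - prog$poses$rz)), 1e-6)
  expect_lt(max(abs(ms$r_z - tr$truth$mma$flex[, 3])), 1e-6)
  # the rig truth itself equals the law-of-cosines closed form (opposite
  # orientation: the truth uses the origin-to-insertion force direction)
  keep <- abs(prog$poses$rz) > 1
  cf <- hinge_moment_arm(12, 30, prog$poses$rz[keep])
  expect_lt(max(abs(tr$truth$mma$flex[keep, 3] - (-cf))), 1e-9)
  # static trial: constant series
  st <- simulate_trial(rig, sweep_program("rz", 25, 25, n_frames = 10))
  mst <- mma_time_series(st, jd, c("flex_prox", "flex_dist"))
  expect_lt(diff(range(mst$r_z)), 1e-9)
})

test_that("missing muscle markers are reported with frame indices", {
  rig <- hinge_flexor_rig()
  tr <- simulate_trial(rig, sweep_program("rz", 0, 30, n_frames = 10))
  tr$markers$flex_dist[c(3, 7), ] <- NA
  expect_error(mma_time_series(tr, joint_definition("proximal", "distal"),
                               c("flex_prox", "flex_dist")),
               "frame\\(s\\): 3, 7")
  expect_error(mma_time_series(tr, joint_definition("proximal", "distal"),
                               c("flex_prox", "nope")), "not in trial")
})

test_that("axes may be evaluated on the proximal or the distal segment", {
  rig <- hinge_flexor_rig()
  tr <- simulate_trial(rig, sweep_program("rz", -40, 40, n_frames = 30))
  mp <- mma_time_series(tr, joint_definition("proximal", "distal"),
                        c("flex_prox", "flex_dist"))
  md <- mma_time_series(tr, joint_definition("proximal", "distal",
                                             axes_from = "distal"),
                        c("flex_prox", "flex_dist"))
  # the hinge axis itself is shared, so r_z agrees; the in-plane axes spin
  expect_equal(mp$r_z, md$r_z, tolerance = 1e-9)
})

test_that("joint types restrict the pose coordinates they accept", {
  rig <- synthetic_rig("revolute")
  expect_error(rig_distal_transform(rig, c(rx = 10)), "not admitted")
  ball <- synthetic_rig("ball")
  expect_error(rig_distal_transform(ball, c(tx = 2)), "not admitted")
  free <- synthetic_rig("free")
  Tf <- rig_distal_transform(free, c(rx = 10, rz = -5, tx = 2, ty = 1))
  expect_s3_class(Tf, "rigid_transform")
})

test_that("pooling several coupled-motion trials widens per-axis extremes beyond single sweeps", {
  rig <- synthetic_rig("free",
                       muscles = list(m = list(origin = c(0, 30, 0),
                                               insertion = c(15, 5, 0))))
  jd <- joint_definition("proximal", "distal")
  # flexion-extension cycles performed at different abduction and
  # translation offsets, as in a manipulation session
  offsets <- list(c(rx = 0, tx = 0), c(rx = 25, tx = 4), c(rx = -20, tx = -4))
  per_trial <- lapply(offsets, function(off) {
    prog <- sweep_program("rz", -30 + off[["rx"]], 30 + off[["rx"]],
                          n_frames = 40,
                          base_pose = off)
    tr <- simulate_trial(rig, prog, noise_sd = 0)
    ms <- mma_time_series(tr, jd, c("m_prox", "m_dist"))
    range_records("S", "L", "j", "rz", min(ms$rz), max(ms$rz))
  })
  pooled <- pooled_range(do.call(rbind, per_trial))
  singles <- vapply(per_trial, function(r) r$max - r$min, numeric(1))
  expect_gt(pooled[["total"]], max(singles))
})
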