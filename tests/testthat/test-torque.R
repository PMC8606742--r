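test_that("maximum isometric force is PCSA times specific tension", {
  expect_equal(max_isometric_force(100), 30)
  expect_equal(max_isometric_force(1), 0.3)
  expect_equal(max_isometric_force(84), 2 * max_isometric_force(42))
  expect_error(max_isometric_force(-5), "positive")
})

test_that("default musculotendon curves satisfy their structural constraints", {
  cv <- mt_curves()
  expect_equal(cv$active(1), 1)
  l <- seq(0.3, 1.8, by = 0.05)
  expect_true(all(cv$active(l) <= 1 + 1e-12))
  expect_true(all(cv$active(l) >= 0))
  expect_true(all(cv$passive(seq(0, 1, by = 0.05)) == 0))  # slack and below
  expect_true(all(diff(cv$passive(seq(1, 1.6, by = 0.05))) > 0))
  expect_equal(cv$tendon(1), 0)
  expect_true(all(cv$tendon(seq(0.9, 1.2, 0.05)) >= 0))
  tab <- tabulated_curve(c(0.5, 1, 1.5), c(0, 1, 0))
  expect_equal(tab(1), 1)
  expect_equal(tab(0.75), 0.5)
  expect_equal(tab(3), 0)  # clamped
})

test_that("isometric torque multiplies out term by term", {
  arch <- muscle_architecture(pcsa = 120, optimal_fibre_length = 25,
                              tendon_slack_length = 10, pennation = 20)
  cv <- mt_curves()
  expect_equal(isometric_torque(8, arch, cv, 1, 1),
               8 * arch$f_max * cos(20 * pi / 180), tolerance = 1e-12)
  expect_identical(isometric_torque(0, arch, cv, 0.8, 0.5), 0)
  set.seed(71)
  for (i in 1:50) {
    r <- rnorm(1, sd = 10); l <- runif(1, 0.5, 1.5); a <- runif(1)
    got <- isometric_torque(r, arch, cv, l, a)
    want <- r * arch$f_max * (a * cv$active(l) + cv$passive(l)) *
      cos(arch$pennation * pi / 180)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(isometric_torque(5, arch, cv, 1, 1.2), "activation")
})

test_that("torque is linear in activation while passive force is zero", {
  arch <- muscle_architecture(50, 20)
  cv <- mt_curves()
  l <- 0.9  # below slack engagement
  t1 <- isometric_torque(5, arch, cv, l, 0.25)
  t2 <- isometric_torque(5, arch, cv, l, 0.5)
  t4 <- isometric_torque(5, arch, cv, l, 1)
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
  expect_equal(t4, 4 * t1, tolerance = 1e-12)
})

test_that("normalised fibre length follows the rigid-tendon model", {
  arch <- muscle_architecture(50, 20, tendon_slack_length = 15,
                              pennation = 30)
  lmt <- 40
  expect_equal(normalised_fibre_length(lmt, arch),
               (40 - 15) / cos(30 * pi / 180) / 20, tolerance = 1e-12)
  expect_identical(normalised_fibre_length(10, arch), 0)  # floored
})

test_that("multi-head muscles are averaged before summation", {
  s <- list(a1 = c(1, 2), a2 = c(3, 4), b = c(10, 10))
  got <- summed_series(s, head_groups = list(a = c("a1", "a2")))
  expect_equal(got, c(12, 13))
  # two identical single-head muscles sum to twice each
  expect_equal(summed_series(list(x = c(1, 1), y = c(1, 1))), c(2, 2))
  # one muscle with two identical heads contributes once
  expect_equal(summed_series(list(h1 = c(3, 3), h2 = c(3, 3)),
                             head_groups = list(m = c("h1", "h2"))),
               c(3, 3))
  expect_error(summed_series(list(a = 1:3, b = 1:4)), "different lengths")
  expect_error(summed_series(list(a = 1:3), head_groups = list(g = "zz")),
               "not in series")
})

test_that("grouped summation matches a brute-force oracle on random groupings", {
  set.seed(72)
  for (rep in 1:20) {
    k <- sample(4:8, 1)
    series <- stats::setNames(lapply(1:k, function(i) rnorm(12)),
                              paste0("s", 1:k))
    in_groups <- sample(names(series), sample(2:k, 1))
    splits <- split(in_groups,
                    sample(1:2, length(in_groups), replace = TRUE))
    groups <- stats::setNames(splits, paste0("g", seq_along(splits)))
    got <- summed_series(series, groups)
    want <- numeric(12)
    for (g in groups) {
      want <- want + Reduce(`+`, series[unlist(g)]) / length(unlist(g))
    }
    for (nm in setdiff(names(series), unlist(groups))) want <- want + series[[nm]]
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("peak ranking orders by absolute peak with alphabetical ties", {
  s <- list(roll = c(0, -3, 1), yaw = c(2, 0, 0), pitch = c(1, 1, 0))
  rk <- peak_rank_order(s)
  expect_equal(rk$motion, c("roll", "yaw", "pitch"))
  expect_equal(rk$peak, c(3, 2, 1))
  tie <- peak_rank_order(list(b = c(2), a = c(-2)))
  expect_equal(tie$motion, c("a", "b"))
})

test_that("equal PCSAs with unit curves preserve the moment-arm ranking; a large PCSA flips a pair", {
  unit_curves <- mt_curves(active = function(l) rep(1, length(l)),
                           passive = function(l) rep(0, length(l)))
  angles <- seq(-60, 60, by = 5)
  mma <- list(
    adduction = -8 * cos(angles * pi / 180),
    flexion = 6 + 0 * angles,
    internal_rotation = 9 + 0.01 * angles,
    abduction = 3 * abs(sin(angles * pi / 180)))
  equal_arch <- muscle_architecture(100, 20)
  torque_equal <- lapply(mma, function(r) {
    isometric_torque(r, equal_arch, unit_curves, 1, 1)
  })
  r_mma <- peak_rank_order(mma)
  r_tq <- peak_rank_order(torque_equal)
  expect_identical(r_mma$motion, r_tq$motion)
  expect_true(compare_rank_orders(r_mma, r_tq)$identical)

  # give the flexion-dominant muscle a much larger PCSA: flexion should
  # overtake adduction (the second-vs-fourth swap phenomenon)
  archs <- list(adduction = equal_arch, flexion = muscle_architecture(160, 20),
                internal_rotation = muscle_architecture(130, 20),
                abduction = equal_arch)
  torque_big <- lapply(names(mma), function(m) {
    isometric_torque(mma[[m]], archs[[m]], unit_curves, 1, 1)
  })
  names(torque_big) <- names(mma)
  cmp <- compare_rank_orders(r_mma, peak_rank_order(torque_big))
  expect_false(cmp$identical)
  expect_setequal(cmp$moved$motion, c("adduction", "flexion"))
})
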