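test_that("lubrication torques have the stated zeros and magnitudes", {
  p <- squirmer_params(beta = 0.7)
  e12 <- c(1, 0, 0)
  # aligned with the line of centres: zero torque
  expect_equal(torque_own_flow(e12, e12, 0.5, p), c(0, 0, 0))
  # perpendicular: magnitude (12/5) pi mu R^2 v0 (-ln eps)
  tq <- torque_own_flow(c(0, 1, 0), e12, 0.5, p)
  expect_equal(sqrt(sum(tq^2)), (12 / 5) * pi * (-log(0.5)), tolerance = 1e-12)
  # prefactor zero when beta e1.e12 = -1
  pb <- squirmer_params(beta = -2)
  e1 <- c(0.5, sqrt(1 - 0.25), 0)  # e1 . e12 = 1/2 = -1/beta
  expect_equal(torque_own_flow(e1, e12, 0.3, pb), c(0, 0, 0),
               tolerance = 1e-12)
  expect_error(torque_own_flow(e12, e12, 1.2, p), "eps")
})

test_that("back-reaction torque is one quarter of the own-flow torque", {
  set.seed(9)
  p <- squirmer_params(beta = 1.4)
  for (i in 1:50) {
    e1 <- random_unit(); e12 <- random_unit(); eps <- runif(1, 0.05, 0.9)
    # flow of 1 in presence of 2: torque on 1 (own) vs torque on 2 (other)
    g_own <- torque_own_flow(e1, e12, eps, p)
    g_other <- torque_other_flow(e1, -(-e12), eps, p)  # flow of 1 acting on 2
    expect_equal(g_other, g_own / 4, tolerance = 1e-12)
  }
})

test_that("torques scale with -ln(eps) and rotate covariantly", {
  p <- squirmer_params(beta = -0.9)
  e1 <- random_unit(); e12 <- random_unit()
  t1 <- torque_own_flow(e1, e12, exp(-1), p)
  t2 <- torque_own_flow(e1, e12, exp(-2), p)
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
  set.seed(14)
  for (i in 1:20) {
    Q <- random_rotation()
    e1 <- random_unit(); e12 <- random_unit()
    a <- as.vector(Q %*% torque_own_flow(e1, e12, 0.4, p))
    b <- torque_own_flow(as.vector(Q %*% e1), as.vector(Q %*% e12), 0.4, p)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("wall torque reduces to the near-field fixed-point structure", {
  for (b in c(-1.5, 0.5, 2)) {
    p <- squirmer_params(beta = b)
    for (th in c(-1, 0.4, 1.2)) {
      e1 <- c(cos(th), sin(th), 0)
      tq <- wall_torque(e1, 0.3, p)
      expect_equal(tq[1:2], c(0, 0), tolerance = 1e-12)
      expect_equal(tq[3],
                   (24 / 5) * pi * (-log(0.3)) * cos(th) * (1 - b * sin(th)),
                   tolerance = 1e-12)
    }
    # same theta-dependence as the near-field angular velocity
    th <- 0.8
    ratio1 <- wall_torque(c(cos(th), sin(th), 0), 0.3, p)[3] /
      nearfield_angular_velocity(th, p)
    th2 <- -0.5
    ratio2 <- wall_torque(c(cos(th2), sin(th2), 0), 0.3, p)[3] /
      nearfield_angular_velocity(th2, p)
    expect_equal(ratio1, ratio2, tolerance = 1e-10)
    expect_gt(ratio1, 0)
  }
  # upright: zero torque; strong puller tilt arcsin(1/beta): zero torque
  p2 <- squirmer_params(beta = 2)
  expect_equal(wall_torque(c(0, 1, 0), 0.4, p2), c(0, 0, 0), tolerance = 1e-12)
  th <- asin(1 / 2)
  expect_equal(wall_torque(c(cos(th), sin(th), 0), 0.4, p2), c(0, 0, 0),
               tolerance = 1e-12)
  # wall coefficient is exactly twice the own-flow sphere coefficient
  e1 <- c(0, 0, 1)
  tw <- wall_torque(e1, 0.3, p2, wall_normal = c(0, 1, 0))
  to <- torque_own_flow(e1, c(0, -1, 0), 0.3, p2)
  expect_equal(tw, 2 * to, tolerance = 1e-12)
})

test_that("preferred pair orientations split at |beta| = 1", {
  expect_equal(preferred_pair_orientation(0.5), "facing_opposite")
  expect_equal(preferred_pair_orientation(0), "facing_opposite")
  expect_equal(preferred_pair_orientation(-2), "aligned_any")
  expect_equal(preferred_pair_orientation(2), "parallel")
})
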