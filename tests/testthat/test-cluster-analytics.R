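test_that("planar ring torque: zeros, oddness, single-perturbation reduction", {
  p <- squirmer_params(beta = 1.2)
  expect_equal(planar_torque(0, 0, 0, 6, 0.5, p), 0)
  set.seed(31)
  for (i in 1:50) {
    N <- sample(2:9, 1)
    tau <- runif(1, -1, 1)
    pb <- squirmer_params(beta = runif(1, -2, 2))
    # odd under mirror reflection (sign flip with neighbours exchanged)
    a <- planar_torque(0.2, tau, -0.1, N, 0.4, pb)
    b <- planar_torque(0.1, -tau, -0.2, N, 0.4, pb)
    expect_equal(a, -b, tolerance = 1e-12)
    # and plain oddness for symmetric neighbour deviations
    expect_equal(planar_torque(0.15, tau, 0.15, N, 0.4, pb),
                 -planar_torque(-0.15, -tau, -0.15, N, 0.4, pb),
                 tolerance = 1e-12)
    # single perturbed swimmer: closed-form reduction
    expect_equal(planar_torque(0, tau, 0, N, 0.4, pb),
                 planar_perturbation_torque(tau, N, 0.4, pb),
                 tolerance = 1e-12)
  }
})

test_that("planar azimuthal criterion across ring sizes", {
  expect_equal(criterion_azimuthal_2d(2)$beta_c, -1)
  expect_equal(criterion_azimuthal_2d(2)$side, "pusher")
  expect_equal(criterion_azimuthal_2d(3)$beta_c, -sqrt(3), tolerance = 1e-12)
  expect_equal(criterion_azimuthal_2d(4)$side, "none")
  expect_equal(criterion_azimuthal_2d(4)$threshold, Inf)
  expect_equal(criterion_azimuthal_2d(6)$beta_c, 1, tolerance = 1e-12)
  expect_equal(criterion_azimuthal_2d(6)$side, "puller")
  expect_equal(criterion_azimuthal_2d(5)$beta_c, sin(pi / 5) / cos(2 * pi / 5),
               tolerance = 1e-12)
})

test_that("scalar polar torque components have the stated signs", {
  p <- squirmer_params(beta = 1.5)  # puller
  expect_equal(unname(polar_torques(0, 0, 6, 0.5, p)), c(0, 0))
  # small positive tilt: own term positive (destabilising) for pullers
  expect_gt(polar_torques(0.1, 0, 6, 0.5, p)["own"], 0)
  # neighbour term carries the sign of the neighbour's tilt
  expect_gt(polar_torques(0, 0.2, 6, 0.5, p)["from_neighbour"], 0)
  expect_lt(polar_torques(0, -0.2, 6, 0.5, p)["from_neighbour"], 0)
})

test_that("uniform polar equilibrium angle of bulk pullers", {
  expect_equal(stable_polar_angle(6, 2), pi)          # beta sin = 1 boundary
  expect_equal(stable_polar_angle(6, 4), 2 * pi / 3)  # arccos(-1/2)
  expect_equal(stable_polar_angle(6, 1.5), pi)        # below threshold
})

test_that("tilted azimuthal criterion for dimers and trimers", {
  expect_equal(criterion_tilted_azimuthal(2, 0), 1)
  expect_equal(criterion_tilted_azimuthal(3, 0), sqrt(3), tolerance = 1e-12)
  expect_equal(criterion_tilted_azimuthal(2, pi / 3), 2, tolerance = 1e-12)
  expect_gt(criterion_tilted_azimuthal(2, 1.5), 10)
  expect_error(criterion_tilted_azimuthal(2, pi / 2), "polar")
  expect_error(criterion_tilted_azimuthal(5, 0.1), "N = 2 or 3")
})

test_that("wall tilt equilibrium: wall-dominated limit and existence", {
  # L -> 0: root tends to arcsin(1/beta) for beta > 1
  for (b in c(1.5, 2.5)) {
    th <- wall_tilt_equilibrium(6, b, 1e-8)
    expect_equal(th[1], asin(1 / b), tolerance = 1e-4)
  }
  # no equilibrium for beta < 1 in the wall-dominated limit
  expect_length(wall_tilt_equilibrium(6, 0.8, 1e-8), 0)
  # smallest beta admitting a tilt equilibrium grows with L (needs a
  # stronger puller to hold the tilt when neighbours matter more)
  beta_min <- function(L) {
    bs <- seq(1, 6, by = 0.02)
    bs[which(vapply(bs, function(b) length(wall_tilt_equilibrium(6, b, L)) > 0,
                    logical(1)))[1]]
  }
  expect_true(beta_min(0.2) <= beta_min(0.5))
  expect_true(beta_min(0.5) <= beta_min(0.9))
})

test_that("contact azimuthal threshold decreases to 1 for large rings", {
  expect_equal(criterion_contact_azimuthal(6), sqrt(2), tolerance = 1e-12)
  expect_equal(criterion_contact_azimuthal(5),
               sqrt(1 + sin(pi / 5) / cos(2 * pi / 5)), tolerance = 1e-12)
  Ns <- c(5, 6, 8, 12, 24, 100)
  v <- vapply(Ns, criterion_contact_azimuthal, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_equal(v[length(v)], 1, tolerance = 0.05)
  expect_error(criterion_contact_azimuthal(4), "N >= 5")
})

test_that("confined polar threshold and its pole", {
  expect_equal(criterion_confined_polar(6, 0), 0)
  expect_equal(criterion_confined_polar(6, 1), 2.5 / 6.75, tolerance = 1e-12)
  L_pole <- 8 / (5 * sin(pi / 6)^2)
  expect_equal(criterion_confined_polar(6, L_pole + 0.01), Inf)
})

test_that("numeric polar threshold of the pusher trimer", {
  # full vector-torque linearisation; the common factor 1 + beta sin(pi/N)
  # puts the trimer threshold at -1/sin(pi/3) = -2/sqrt(3)
  thr <- polar_stability_threshold(3)
  expect_equal(thr, -2 / sqrt(3), tolerance = 1e-6)
})

test_that("criteria table collects applicable thresholds", {
  tb <- stability_criteria(6, L = 1)
  expect_setequal(tb$criterion,
                  c("azimuthal_2d", "contact_azimuthal", "confined_polar"))
  tb2 <- stability_criteria(2)
  expect_equal(nrow(tb2), 1)
})
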