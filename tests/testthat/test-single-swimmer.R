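test_that("wall-corrected sedimentation speed behaves", {
  p <- squirmer_params(beta = 0.5, alpha = 0.77)
  expect_equal(sedimentation_speed(1e9, p), p$vg, tolerance = 1e-8)
  expect_equal(sedimentation_speed(1, p), 0.375 * p$vg)
  # the third-order truncation is monotone increasing away from contact
  # (the bracket's derivative changes sign at R/h = sqrt(3/4))
  h <- seq(1.16, 100, length.out = 400)
  expect_true(all(diff(sedimentation_speed(h, p)) > 0))
  expect_lt(sedimentation_speed(1.1547, p), sedimentation_speed(1, p))
  expect_error(sedimentation_speed(0.5, p), "h >= R")
})

test_that("vertical velocity limits and roots", {
  p <- squirmer_params(beta = 0.5, alpha = 0.77)
  th <- 0.3
  expect_equal(vertical_velocity(1e8, th, p), p$v0 * (sin(th) - 1 / p$alpha),
               tolerance = 1e-6)
  # beta = 0, theta = pi/2, alpha = 1: u_z = v0[-(R/h)^3 + (9/8)(R/h)] > 0
  # for all h > R (reduced cubic has no root with R/h < 1)
  p0 <- squirmer_params(beta = 0, alpha = 1)
  h <- seq(1.01, 50, length.out = 300)
  expect_true(all(vertical_velocity(h, pi / 2, p0) > 0))
})

test_that("far-field orientation fixed points and stability", {
  # pusher: upright at the matching height, tilted beyond it
  b <- -0.5
  p <- squirmer_params(beta = b, alpha = 0.77)
  h_match <- 2 / (3 * abs(b))
  eo <- equilibrium_orientation_farfield(h_match * 0.99, p)
  up <- eo[eo$branch == "upright", ]
  expect_true(up$stable)
  eo2 <- equilibrium_orientation_farfield(h_match * 1.2, p)
  expect_false(eo2$stable[eo2$branch == "upright"])
  tl <- eo2[eo2$branch == "tilted", ]
  expect_equal(tl$theta, asin(-2 / (3 * b * h_match * 1.2)), tolerance = 1e-12)
  expect_true(tl$stable)
  # tilt goes to zero far from the wall
  eo3 <- equilibrium_orientation_farfield(1e6, p)
  expect_equal(eo3$theta[eo3$branch == "tilted"], 0, tolerance = 1e-5)
  # puller beta = 1 at h = R: downward stable since beta > 2R/(3h)
  pp <- squirmer_params(beta = 1, alpha = 0.77)
  eo4 <- equilibrium_orientation_farfield(1, pp)
  expect_true(eo4$stable[eo4$branch == "downward"])
  expect_true(eo4$stable[eo4$branch == "upright"])
})

test_that("combined equilibria reproduce the known regimes", {
  expect_equal(combined_equilibrium(0.77, -0.5)$regime, "tilted_swimming")
  up <- combined_equilibrium(0.77, 1)
  expect_equal(up$regime, "upright_floating")
  expect_equal(up$theta_star, pi / 2)
  expect_true(up$farfield_valid)
  expect_equal(combined_equilibrium(0.77, -2)$regime, "oscillatory_none")
  expect_equal(combined_equilibrium(0.3, 1)$regime, "sunk_nearfield")
})

test_that("stable equilibria are genuine fixed points with negative slopes", {
  for (cs in list(c(0.77, 1), c(0.77, -0.5), c(1.2, -0.8), c(0.9, 0.3))) {
    ce <- combined_equilibrium(cs[1], cs[2])
    if (is.na(ce$h_star)) next
    p <- squirmer_params(beta = cs[2], alpha = cs[1])
    expect_lt(abs(vertical_velocity(ce$h_star, ce$theta_star, p)), 1e-9)
    expect_lt(abs(squirmers:::.farfield_dtheta(ce$h_star, ce$theta_star, p)),
              1e-9)
    d <- 1e-6
    duz <- (vertical_velocity(ce$h_star + d, ce$theta_star, p) -
              vertical_velocity(ce$h_star - d, ce$theta_star, p)) / (2 * d)
    expect_lt(duz, 0)
    dom <- (squirmers:::.farfield_dtheta(ce$h_star, ce$theta_star + d, p) -
              squirmers:::.farfield_dtheta(ce$h_star, ce$theta_star - d, p)) / (2 * d)
    expect_lt(dom, 0)
  }
})

test_that("upright/tilted boundary curve separates the regimes", {
  expect_equal(alpha_tilt_boundary(0), 1)
  for (b in c(-0.1, -0.2, -0.3)) {
    a_star <- alpha_tilt_boundary(b)
    expect_equal(combined_equilibrium(a_star - 0.02, b)$regime,
                 "upright_floating")
    expect_equal(combined_equilibrium(a_star + 0.02, b)$regime,
                 "tilted_swimming")
  }
})

test_that("phase diagram tabulates regimes on a grid", {
  pd <- phase_diagram(alpha = seq(0.6, 1.4, by = 0.1),
                      beta = seq(-1.5, 1.5, by = 0.25))
  expect_s3_class(pd, "squirmer_phase_diagram")
  expect_setequal(setdiff(unique(pd$regime), NA),
                  intersect(unique(pd$regime),
                            c("upright_floating", "tilted_swimming",
                              "oscillatory_none", "sunk_nearfield")))
  expect_true(all(is.na(pd$h_star) | pd$h_star > 0))
  # regions on either side of the boundary show the expected states
  expect_equal(pd$regime[pd$alpha == 0.8 & pd$beta == 1], "upright_floating")
  expect_equal(pd$regime[pd$alpha == 0.8 & pd$beta == -0.5], "tilted_swimming")
  expect_equal(pd$regime[pd$alpha == 1.4 & pd$beta == -1.5],
               "oscillatory_none")
})

test_that("near-field fixed points depend only on beta", {
  p2 <- squirmer_params(beta = 2)
  expect_equal(nearfield_angular_velocity(pi / 2, p2), 0)
  fp <- nearfield_fixed_points(2)
  tl <- fp[fp$branch == "tilted", ]
  expect_equal(tl$theta, pi / 6, tolerance = 1e-12)
  expect_true(tl$stable)
  expect_true(nearfield_fixed_points(0.5)$stable[1])  # upright for beta < 1
  expect_false(nearfield_fixed_points(1.5)$stable[1]) # upright for beta > 1
  fp_push <- nearfield_fixed_points(-1.5)
  expect_true(fp_push$stable[fp_push$branch == "downward"])
  fp_weak <- nearfield_fixed_points(-0.5)
  expect_false(fp_weak$stable[fp_weak$branch == "downward"])
})
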