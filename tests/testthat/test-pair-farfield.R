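test_that("pair rates reduce to the single-swimmer values as D grows", {
  p <- squirmer_params(beta = 0.8, alpha = 0.77)
  h <- 3.1; th <- 1.1
  st <- pair_state(1e5, h, th)
  # angular rate -> half the own-image vorticity
  expect_equal(pair_angular_velocity(st, p),
               squirmers:::.farfield_dtheta(h, th, p), tolerance = 1e-8)
  v <- pair_velocity(st, p)
  # wall image term is D-independent
  st2 <- pair_state(7, h, th)
  v2 <- pair_velocity(st2, p)
  expect_equal(v$wall, v2$wall, tolerance = 1e-12)
  # direct and image-of-other terms vanish at infinity
  expect_lt(max(abs(v$direct)), 1e-9)
  expect_lt(max(abs(v$image_other)), 1e-9)
})

test_that("direct velocity from the partner matches the closed form at pi/2", {
  p <- squirmer_params(beta = -0.7, alpha = 0.77)
  D <- 6
  st <- pair_state(D, 4, pi / 2)
  v <- pair_velocity(st, p)
  expect_equal(v$direct[1], p$p / D^2, tolerance = 1e-12)
  expect_equal(v$direct[2], -p$s / D^3, tolerance = 1e-12)
})

test_that("compiled pair rates equal the R assembly", {
  set.seed(21)
  for (i in 1:10) {
    p <- squirmer_params(beta = runif(1, -1, 1.5), alpha = 0.77)
    D <- runif(1, 3, 15); h <- runif(1, 2.2, 6); th <- runif(1, 0.2, 1.4)
    st <- pair_state(D, h, th)
    v <- pair_velocity(st, p)
    w <- pair_angular_velocity(st, p)
    cc <- squirmers:::.pair_rates_cpp(D, h, th, p$p, p$s, p$v0, p$vg, p$R)
    expect_equal(cc, c(v$total[1], v$total[2], w), tolerance = 1e-12)
  }
})

test_that("mirror symmetry: swimmer 2 rates reflect swimmer 1", {
  p <- squirmer_params(beta = 1.1, alpha = 0.77)
  st <- pair_state(5.5, 3.2, 1.2)
  amb1 <- squirmers:::.pair_ambient(st$x1, st$e1, st$x2, st$e2, p)
  amb2 <- squirmers:::.pair_ambient(st$x2, st$e2, st$x1, st$e1, p)
  u1 <- amb1$u_wall + amb1$u_direct + amb1$u_image_other
  u2 <- amb2$u_wall + amb2$u_direct + amb2$u_image_other
  expect_equal(u2[1], -u1[1], tolerance = 1e-12)
  expect_equal(u2[2], u1[2], tolerance = 1e-12)
  expect_equal(amb2$vorticity[3], -amb1$vorticity[3], tolerance = 1e-12)
})

test_that("repulsion velocity has the stated structure", {
  p <- squirmer_params(beta = -0.5, alpha = 0.77)
  expect_equal(repulsion_velocity(pair_state(4, 3, pi / 2), p), 0)
  expect_equal(repulsion_velocity(pair_state(2.5, 3, 0), p), -1)
  expect_error(repulsion_velocity(pair_state(1.9, 3, 0), p), "contact")
})

test_that("fixed-distance relaxation reproduces the pair equilibria", {
  # far separation returns the single-swimmer equilibrium
  p <- squirmer_params(beta = 1, alpha = 0.77)
  ce <- combined_equilibrium(0.77, 1)
  r <- relax_fixed_distance(60, p)
  expect_equal(r$h, ce$h_star, tolerance = 1e-2)
  expect_equal(r$theta, ce$theta_star, tolerance = 1e-2)
  # pullers at close range tilt towards each other and sink, continuously
  r5 <- relax_fixed_distance(5, p)
  r4 <- relax_fixed_distance(4, p)
  expect_lt(r4$theta, r5$theta)
  expect_lt(r5$theta, pi / 2)
  expect_lt(r4$h, r5$h)
  expect_lt(r5$h, ce$h_star)
  # pushers below the lift-off distance flip slightly past upright and rise
  ps <- squirmer_params(beta = -0.5, alpha = 0.77)
  cep <- combined_equilibrium(0.77, -0.5)
  rp <- relax_fixed_distance(3, ps)
  expect_gt(rp$theta, pi / 2)
  expect_gt(rp$h, cep$h_star)
})

test_that("encounters collide or separate as expected", {
  # weak pullers attract from D0 = 5: collide after sinking and tilting
  pl <- squirmer_params(beta = 1, alpha = 0.77)
  enc <- simulate_encounter(5, pl)
  expect_equal(enc$outcome, "collide")
  expect_true(all(enc$trajectory$D >= 2.5))
  last <- enc$trajectory[nrow(enc$trajectory), ]
  first <- enc$trajectory[1, ]
  expect_lt(last$theta, first$theta)  # tilted towards each other
  expect_lt(last$h, first$h)          # sank before contact
  # tilted pushers swim into contact with little reorientation
  ps <- squirmer_params(beta = -0.5, alpha = 0.77)
  encp <- simulate_encounter(10, ps)
  expect_equal(encp$outcome, "collide")
  dth_push <- abs(encp$trajectory$theta[nrow(encp$trajectory)] -
                    encp$trajectory$theta[1])
  dth_pull <- abs(last$theta - first$theta)
  expect_lt(dth_push, dth_pull)
  # pullers beyond the critical distance separate
  enc_far <- simulate_encounter(16, pl)
  expect_equal(enc_far$outcome, "separate")
})

test_that("critical distance: bisection agrees with a dense scan and trends", {
  pl <- squirmer_params(beta = 1, alpha = 0.77)
  dc1 <- critical_distance(pl, D_range = c(3, 30), tol = 0.05)
  # dense-scan oracle: relaxed tilt crosses pi/2 between consecutive D
  ce <- combined_equilibrium(0.77, 1)
  init <- c(h = ce$h_star, theta = ce$theta_star)
  Ds <- seq(floor(dc1) - 1, ceiling(dc1) + 1, by = 0.25)
  tilts <- vapply(Ds, function(D) {
    relax_fixed_distance(D, pl, init = init)$theta
  }, numeric(1))
  k <- which(diff(sign(tilts - pi / 2)) != 0)[1]
  expect_true(Ds[k] <= dc1 && dc1 <= Ds[k + 1] + 0.25)
  # D_c decreases with beta for pullers
  dc2 <- critical_distance(squirmer_params(beta = 2, alpha = 0.77),
                           D_range = c(3, 30), tol = 0.05)
  expect_lt(dc2, dc1)
  # tilted pushers have no repulsive range
  expect_equal(critical_distance(squirmer_params(beta = -0.5, alpha = 0.77),
                                 D_range = c(3, 30), tol = 0.1), Inf)
})
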