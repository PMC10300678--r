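test_that("exactly inward bulk circle is a fixed point without noise", {
  # the pairwise torques cancel by symmetry in the inward configuration
  for (N in c(2, 3, 6, 8)) {
    cfg <- build_circle(N, 0.5)
    for (b in c(-2, -0.5, 1.5)) {
      tq <- cluster_torques(config = cfg, params = squirmer_params(beta = b))
      expect_lt(max(abs(tq)), 1e-12)
    }
  }
  # for dynamically stable configurations the zero-noise drift stays at
  # machine level over 10^4 steps (an unstable one amplifies rounding noise)
  proto <- simulation_protocol(noise_eta = 0, t_max = 100, n_replicates = 1)
  for (cs in list(list(N = 6, b = 1.5), list(N = 2, b = -2))) {
    r <- simulate_cluster(build_circle(cs$N, 0.5), cs$b, proto, mode = "2d")
    expect_true(r$stable)
    expect_lt(r$max_dphi, 1e-9)
  }
  r3 <- simulate_cluster(build_circle(2, 0.5), -2, proto, mode = "3d")
  expect_true(r3$stable)
  expect_lt(r3$max_theta, 1e-9)
})

test_that("orientations stay unit-norm over long noisy runs", {
  cfg <- build_circle(5, 0.5, walls = "bottom", h = 1.4)
  proto <- simulation_protocol(t_max = 1000, n_replicates = 1, seed = 2)
  r <- simulate_cluster(cfg, 2.5, proto, mode = "3d")
  norms <- sqrt(rowSums(r$replicates[[1]]$orientations^2))
  expect_equal(norms, rep(1, 5), tolerance = 1e-12)
})

test_that("reference R stepper matches the compiled kernel", {
  cfg <- build_circle(4, 0.4, walls = "bottom", h = 1.5)
  p <- squirmer_params(beta = -1.3)
  proto <- simulation_protocol(noise_eta = 0, t_max = 1)
  # perturbed start so torques are non-trivial
  ors <- cfg$orientations
  ors[1, ] <- squirmers:::.normalize(ors[1, ] + c(0.05, 0.1, -0.03))
  ors[3, ] <- squirmers:::.normalize(ors[3, ] + c(-0.02, 0.07, 0.04))
  e_r <- ors
  for (k in 1:25) e_r <- step_orientations(cfg, e_r, proto, p)
  np <- neighbour_pairs(cfg)
  wl <- squirmers:::.wall_logs(cfg)
  res <- squirmers:::.cluster_run_cpp(cfg$positions, ors,
                                      cbind(np$i - 1L, np$j - 1L),
                                      -log(np$eps), p$beta, wl$mode,
                                      wl$bottom, wl$top, cfg$inward,
                                      proto$dt, 25L, 0, FALSE, pi / 2, pi / 2,
                                      10L, 0L)
  expect_equal(res$orientations, e_r, tolerance = 1e-12)
})

test_that("planar classifications match the known stability structure", {
  proto <- quick_protocol(t_max = 600)
  # squares never stable
  for (b in c(-2.5, -1, 1, 2.5)) {
    expect_false(simulate_cluster(build_circle(4, 0.5), b, proto,
                                  mode = "2d")$stable)
  }
  # dimers: stable pushers below -1, unstable above
  expect_true(simulate_cluster(build_circle(2, 0.5), -2, proto,
                               mode = "2d")$stable)
  expect_false(simulate_cluster(build_circle(2, 0.5), -0.6, proto,
                                mode = "2d")$stable)
  # puller hexagon: stable above the analytic threshold of 1
  expect_true(simulate_cluster(build_circle(6, 0.5), 1.5, proto,
                               mode = "2d")$stable)
  expect_false(simulate_cluster(build_circle(6, 0.5), 0.6, proto,
                                mode = "2d")$stable)
})

test_that("bulk puller circles break through the polar mode", {
  proto <- quick_protocol(t_max = 600)
  for (N in c(5, 7)) {
    for (b in c(1.2, 2.5)) {
      r <- simulate_cluster(build_circle(N, 0.5), b, proto, mode = "3d")
      expect_false(r$stable)
      expect_true(r$mode %in% c("polar", "mixed"))
    }
  }
})

test_that("a bottom wall stabilises strong-puller circles", {
  proto <- quick_protocol(t_max = 600)
  cfg <- build_circle(6, 0.5, walls = "bottom", h = 1.3)
  expect_true(simulate_cluster(cfg, 3, proto, mode = "3d")$stable)
  expect_false(simulate_cluster(cfg, 1.1, proto, mode = "3d")$stable)
})

test_that("noise and step-size halving do not change classifications", {
  base <- quick_protocol(t_max = 400)
  half_eta <- simulation_protocol(noise_eta = 0.025, t_max = 400,
                                  n_replicates = 2, seed = 11)
  half_dt <- simulation_protocol(dt = 0.005, t_max = 400, n_replicates = 2,
                                 seed = 11)
  cases <- list(list(N = 6, b = 1.5, mode = "2d"),
                list(N = 6, b = 0.6, mode = "2d"),
                list(N = 2, b = -1.6, mode = "2d"))
  for (cs in cases) {
    cfg <- build_circle(cs$N, 0.5)
    s0 <- simulate_cluster(cfg, cs$b, base, mode = cs$mode)$stable
    expect_equal(simulate_cluster(cfg, cs$b, half_eta, mode = cs$mode)$stable,
                 s0, info = "noise halving")
    expect_equal(simulate_cluster(cfg, cs$b, half_dt, mode = cs$mode)$stable,
                 s0, info = "dt halving")
  }
})

test_that("filled and partial clusters are not stable where circles break", {
  proto <- quick_protocol(t_max = 400)
  # bulk pullers: the N = 7 circle is polar-unstable; so are the compact ones
  b <- 2
  expect_false(simulate_cluster(build_circle(7, 0.5), b, proto,
                                mode = "3d")$stable)
  expect_false(simulate_cluster(build_filled_circle(7, 0.5), b, proto,
                                mode = "3d")$stable)
  expect_false(simulate_cluster(build_partial_circle(7, 0.5), b, proto,
                                mode = "3d")$stable)
  # weak-puller square region: partial rhombus also unstable
  expect_false(simulate_cluster(build_partial_circle(4, 0.5), 0.5, proto,
                                mode = "3d")$stable)
})

test_that("threshold bisection recovers the planar analytic limit", {
  proto <- quick_protocol(t_max = 600)
  ts <- threshold_scan(function() build_circle(6, 0.5), c(0.3, 2.5), proto,
                       mode = "2d", resolution = 0.05)
  expect_equal(ts$stable_side, "high")
  expect_equal(ts$beta_c, 1, tolerance = 0.1)
  # no threshold inside an all-stable range
  ts2 <- threshold_scan(function() build_circle(2, 0.5), c(-3, -2.5), proto,
                        mode = "2d", resolution = 0.05)
  expect_true(is.na(ts2$beta_c))
  expect_equal(ts2$stable_side, "all")
})

test_that("exponent fit recovers a synthetic power law exactly", {
  eps <- c(0.05, 0.1, 0.2, 0.4)
  boundary <- tibble::tibble(eps = eps, h = eps^2)
  expect_equal(exponent_fit(boundary)$gamma, 2, tolerance = 1e-12)
  expect_error(exponent_fit(boundary[1:3, ]), "at least 4")
  expect_error(exponent_fit(tibble::tibble(eps = c(0.2, 0.25, 0.3, 0.35),
                                           h = c(0.2, 0.25, 0.3, 0.35)^2)),
               "range")
})

test_that("same protocol seed reproduces runs bit-for-bit", {
  cfg <- build_circle(5, 0.5, walls = "bottom", h = 1.4)
  proto <- quick_protocol(t_max = 100, seed = 99)
  a <- simulate_cluster(cfg, 2, proto, mode = "3d")
  b <- simulate_cluster(cfg, 2, proto, mode = "3d")
  expect_identical(glance(a), glance(b))
  expect_identical(a$replicates[[1]]$orientations,
                   b$replicates[[1]]$orientations)
})
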