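test_that("singularity strengths follow the two-mode squirmer", {
  cases <- list(
    list(beta = 0, v0 = 1, R = 1, p = 0, s = 0.5),
    list(beta = -0.5, v0 = 1, R = 1, p = 0.375, s = 0.5),
    list(beta = 2, v0 = 2, R = 1, p = -3, s = 1)
  )
  for (cs in cases) {
    st <- singularity_strengths(squirmer_params(beta = cs$beta, v0 = cs$v0,
                                                R = cs$R))
    expect_equal(unname(st["p"]), cs$p)
    expect_equal(unname(st["s"]), cs$s)
  }
  # sign(p) = -sign(beta); nondimensional mode p = -3 beta / 4, s = 1/2
  for (b in c(-2, -0.1, 0.3, 1.7)) {
    pp <- squirmer_params(beta = b)
    expect_equal(sign(pp$p), -sign(b))
    expect_equal(pp$p, -3 * b / 4)
    expect_equal(pp$s, 0.5)
  }
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(squirmer_params(beta = 1, R = 0), "R")
  expect_error(squirmer_params(beta = 1, mu = -1), "mu")
  expect_error(squirmer_params(beta = 1, alpha = 0), "alpha")
  expect_equal(squirmer_params(beta = 1, alpha = Inf)$vg, 0)
})

test_that("surface slip matches the boundary condition and its symmetries", {
  p <- squirmer_params(beta = 1)
  e <- c(0, 1, 0)
  # front/back poles: bracket vanishes
  expect_equal(surface_slip(e, e, p), c(0, 0, 0))
  # equator: -(3/2) v0 e for any beta
  for (b in c(-1, 0, 2)) {
    pb <- squirmer_params(beta = b)
    expect_equal(surface_slip(e, c(1, 0, 0), pb), -1.5 * e)
  }
  # oblique point: |u| = (3/2) v0 (1 + beta c) sqrt(1 - c^2), c = cos(pi/4)
  cc <- cos(pi / 4)
  er <- c(sin(pi / 4), cos(pi / 4), 0)
  u <- surface_slip(e, er, p)
  expect_equal(sqrt(sum(u^2)), 1.5 * (1 + cc) * sqrt(1 - cc^2), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:200) {
    ee <- random_unit(); rr <- random_unit()
    u <- surface_slip(ee, rr, p)
    # tangential to the sphere
    expect_lt(abs(sum(u * rr)), 1e-12)
  }
  # invariance under a common rotation
  set.seed(7)
  for (i in 1:20) {
    ee <- random_unit(); rr <- random_unit(); Q <- random_rotation()
    u1 <- Q %*% surface_slip(ee, rr, p)
    u2 <- surface_slip(as.vector(Q %*% ee), as.vector(Q %*% rr), p)
    expect_equal(as.vector(u1), as.vector(u2), tolerance = 1e-12)
  }
})
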