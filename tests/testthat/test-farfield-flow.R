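test_that("free-space squirmer flow has the stresslet + source-dipole form", {
  p <- squirmer_params(beta = -0.8)
  e <- c(0, 0, 1)
  # along the axis: u = (2p/r^2 + 2s/r^3) rhat
  r <- 3
  u <- squirmer_flow(c(0, 0, r), c(0, 0, 0), e, p)
  expect_equal(u, (2 * p$p / r^2 + 2 * p$s / r^3) * e, tolerance = 1e-12)
  # perpendicular: u = -(p/r^2) rhat - (s/r^3) e
  u <- squirmer_flow(c(r, 0, 0), c(0, 0, 0), e, p)
  expect_equal(u, -(p$p / r^2) * c(1, 0, 0) - (p$s / r^3) * e,
               tolerance = 1e-12)
  # neutral squirmer with no source dipole: zero everywhere
  p0 <- squirmer_params(beta = 0, v0 = 0)
  expect_equal(squirmer_flow(c(1, 2, 3), c(0, 0, 0), e, p0), c(0, 0, 0))
  expect_error(squirmer_flow(c(0, 0, 0), c(0, 0, 0), e, p), "singularity")
})

test_that("analytic vorticity matches the in-plane closed form and FD curl", {
  # p = 1 via beta = -4/3: z-vorticity at (-D,0,0) is 6 p sin cos / D^3
  p1 <- squirmer_params(beta = -4 / 3)
  expect_equal(p1$p, 1)
  th <- pi / 4
  # mirrored pair orientation (-cos, sin, 0) of the swimmer whose flow is
  # evaluated at its partner's position (-D, 0, 0)
  e <- c(-cos(th), sin(th), 0)
  w <- flow_vorticity(c(-2, 0, 0), c(0, 0, 0), e, p1)
  expect_equal(w[3], 0.375, tolerance = 1e-12)
  expect_equal(flow_vorticity(c(-2, 0, 0), c(0, 0, 0), c(1, 0, 0), p1),
               c(0, 0, 0), tolerance = 1e-12)

  set.seed(5)
  pr <- squirmer_params(beta = 1.3)
  for (i in 1:20) {
    x <- c(runif(1, -4, 4), runif(1, -4, 4), runif(1, -4, 4))
    if (sqrt(sum(x^2)) < 0.5) next
    e <- random_unit()
    w <- flow_vorticity(x, c(0, 0, 0), e, pr)
    wn <- num_curl(function(y) squirmer_flow(y, c(0, 0, 0), e, pr), x)
    expect_equal(w, wn, tolerance = 1e-6)
  }
})

test_that("image systems enforce no-slip on the wall", {
  set.seed(8)
  for (i in 1:5) {
    loc <- c(runif(1, -1, 1), runif(1, 0.8, 3), runif(1, -1, 1))
    e <- random_unit()
    for (kind in c("stresslet", "source_dipole")) {
      sc <- singularity_config(kind, strength = 1.7, location = loc, axis = e)
      free <- function(x) {
        if (kind == "stresslet") {
          r <- x - loc; rn <- sqrt(sum(r^2)); rh <- r / rn
          -1.7 / rn^2 * (1 - 3 * sum(e * rh)^2) * rh
        } else {
          r <- x - loc; rn <- sqrt(sum(r^2)); rh <- r / rn
          -1.7 / rn^3 * (e - 3 * sum(e * rh) * rh)
        }
      }
      grid <- expand.grid(x = seq(-5, 5, length.out = 20),
                          z = seq(-5, 5, length.out = 20))
      scale <- sqrt(sum(free(c(0, 0.0, 0) + c(loc[1], 0, loc[3]))^2))
      worst <- max(apply(grid, 1, function(g) {
        xw <- c(g[["x"]], 0, g[["z"]])
        max(abs(free(xw) + image_system_flow(xw, sc)))
      }))
      expect_lt(worst, 1e-10 * scale)
    }
  }
})

test_that("own-image vorticity reproduces the wall reorientation form", {
  # z-curl of the image flow at the swimmer centre:
  # -(6p/8h^3) sin cos + (6s/8h^4) cos
  p <- squirmer_params(beta = 0.9)
  for (h in c(2.2, 3.5)) {
    for (th in c(-0.7, 0.3, 1.2)) {
      e <- c(cos(th), sin(th), 0)
      w <- squirmer_image_vorticity(c(0, h, 0), c(0, h, 0), e, p)
      expect_equal(w[3],
                   -(6 * p$p / (8 * h^3)) * sin(th) * cos(th) +
                     (6 * p$s / (8 * h^4)) * cos(th),
                   tolerance = 1e-10)
      expect_equal(w[1:2], c(0, 0), tolerance = 1e-12)
    }
  }
  # and equals the FD curl of the image flow at off-centre points
  set.seed(3)
  for (i in 1:10) {
    pos <- c(0, runif(1, 1, 3), 0)
    e <- random_unit()
    x <- c(runif(1, -3, 3), runif(1, 0.5, 4), runif(1, -3, 3))
    w <- squirmer_image_vorticity(x, pos, e, p)
    wn <- num_curl(function(y) squirmer_image_flow(y, pos, e, p), x)
    expect_equal(w, wn, tolerance = 1e-5)
  }
})

test_that("image flow is linear in the singularities and decays in rho", {
  p <- squirmer_params(beta = -1.2)
  loc <- c(0.3, 1.4, -0.2)
  e <- random_unit()
  x <- c(2, 1, 1)
  s1 <- singularity_config("stresslet", p$p, loc, e)
  s2 <- singularity_config("source_dipole", p$s, loc, e)
  expect_equal(image_system_flow(x, s1) + image_system_flow(x, s2),
               squirmer_image_flow(x, loc, e, p), tolerance = 1e-12)
  # doubling the strength doubles the flow
  s3 <- singularity_config("stresslet", 2 * p$p, loc, e)
  expect_equal(image_system_flow(x, s3), 2 * image_system_flow(x, s1),
               tolerance = 1e-12)
  # far-field decay at least 1/rho^2
  rho <- c(20, 40)
  mag <- vapply(rho, function(r) {
    sqrt(sum(squirmer_image_flow(c(r, loc[2], 0), loc, e, p)^2))
  }, numeric(1))
  rate <- log(mag[1] / mag[2]) / log(rho[2] / rho[1])
  expect_gt(rate, 2 - 0.1)
})

test_that("sources at or below the wall are rejected", {
  p <- squirmer_params(beta = 1)
  expect_error(squirmer_image_flow(c(0, 1, 0), c(0, -0.5, 0), c(0, 1, 0), p),
               "above the wall")
  expect_error(singularity_config("stresslet", 1, c(0, 0, 0), c(0, 1, 0)),
               "above the wall")
})

test_that("compiled flow kernels agree with the generated R forms", {
  kernels <- c("stresslet_image_u", "sdipole_image_u", "stresslet_image_curl",
               "sdipole_image_curl", "stresslet_free_curl")
  set.seed(12)
  for (i in 1:10) {
    Y <- c(runif(1, -2, 2), runif(1, 0.5, 4), runif(1, -2, 2))
    e <- random_unit()
    x <- c(runif(1, -4, 4), runif(1, 0.2, 5), runif(1, -4, 4))
    for (k in kernels) {
      rf <- get(paste0(".", k), envir = asNamespace("squirmers"))
      expect_equal(rf(x[1], x[2], x[3], Y[1], Y[2], Y[3], e[1], e[2], e[3]),
                   squirmers:::.flow_kernel_cpp(k, x, Y, e),
                   tolerance = 1e-12, info = k)
    }
  }
})
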