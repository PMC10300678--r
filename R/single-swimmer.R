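#' Wall-corrected sedimentation speed
#'
#' Settling speed of a passive sphere at height `h` above a rigid wall,
#' `vg * (1 - 9R/(8h) + (R/h)^3 / 2)`, directed towards the wall. Tends to
#' the bulk speed `vg = v0 / alpha` as `h` grows and is reduced by wall drag
#' near contact.
#'
#' @param h height of the sphere centre above the wall (same units as `R`).
#' @param params a [squirmer_params()] object.
#' @return Settling speed (positive scalar; the velocity is `-speed * ey`).
#' @export
sedimentation_speed <- function(h, params) {
  if (any(h < params$R)) stop("sedimentation_speed requires h >= R")
  x <- params$R / h
  params$vg * (1 - 9 * x / 8 + x^3 / 2)
}

#' Total vertical velocity of a squirmer above a wall (far field)
#'
#' Vertical velocity combining self-propulsion, gravity, and wall-induced
#' hydrodynamic interaction, to third order in `R/h`:
#' \deqn{u_z = v_0[ -(R/h)^3 (\sin\theta + \alpha^{-1})/2
#'   + (R/h)^2 (9\beta/32)(1 - 3\sin^2\theta)
#'   + (R/h)(9/8)\alpha^{-1} + \sin\theta - \alpha^{-1} ].}
#'
#' @param h height of the centre above the wall.
#' @param theta orientation angle from the horizontal (radians).
#' @param params a [squirmer_params()] object.
#' @return Vertical velocity (positive upwards).
#' @export
vertical_velocity <- function(h, theta, params) {
  if (any(h <= 0)) stop("h must be positive")
  x <- params$R / h
  ia <- 1 / params$alpha
  st <- sin(theta)
  params$v0 * (-x^3 * 0.5 * (st + ia) +
                 x^2 * (9 * params$beta / 32) * (1 - 3 * st^2) +
                 x * (9 / 8) * ia + st - ia)
}

# far-field wall-induced reorientation rate dtheta/dt (half the vorticity of
# the swimmer's own image system at its centre):
#   0.5 * [ -(6p/8h^3) sin t cos t + (6s/8h^4) cos t ]
.farfield_dtheta <- function(h, theta, params) {
  0.5 * (-(6 * params$p / (8 * h^3)) * sin(theta) * cos(theta) +
           (6 * params$s / (8 * h^4)) * cos(theta))
}

.farfield_dtheta_dtheta <- function(h, theta, params) {
  A <- -(6 * params$p / (8 * h^3))
  B <- 6 * params$s / (8 * h^4)
  0.5 * (A * cos(2 * theta) - B * sin(theta))
}

#' Far-field equilibrium orientations at fixed height
#'
#' Fixed points in orientation of a squirmer held at height `h` above the
#' wall, from the vorticity of its own wall image. Upright and downward
#' vertical states are always fixed points; a tilted fixed point with
#' `sin(theta) = -2R/(3 beta h)` exists when that value lies in `[-1, 1]`.
#' Stability is classified by the sign of the angular-rate derivative:
#' pushers tilt once `h > 2R/(3|beta|)`, pullers are stable upright at every
#' height, and the downward puller state is stable for `beta > 2R/(3h)`.
#'
#' @param h height of the centre above the wall.
#' @param params a [squirmer_params()] object.
#' @return Tibble with columns `theta`, `stable`, `branch`.
#' @export
equilibrium_orientation_farfield <- function(h, params) {
  stopifnot(h > 0)
  cand <- tibble::tibble(theta = c(pi / 2, -pi / 2),
                         branch = c("upright", "downward"))
  if (params$beta != 0) {
    st <- -2 * params$R / (3 * params$beta * h)
    if (abs(st) <= 1) {
      cand <- dplyr::bind_rows(cand,
                               tibble::tibble(theta = asin(st), branch = "tilted"))
    }
  }
  cand$stable <- vapply(cand$theta,
                        function(t) .farfield_dtheta_dtheta(h, t, params) < 0,
                        logical(1))
  cand
}

# real roots of a polynomial (ascending coefficients) in the open interval
.real_roots_in <- function(coefs, lower, upper, tol = 1e-9) {
  coefs <- coefs[seq_len(max(which(abs(coefs) > 0)))]
  if (length(coefs) < 2) return(numeric(0))
  z <- polyroot(coefs)
  x <- Re(z[abs(Im(z)) < 1e-7 * (1 + abs(Re(z)))])
  sort(unique(x[x > lower + tol & x < upper - tol]))
}

# d u_z / d x at fixed theta, x = R/h (u_z increasing in x at fixed theta
# means u_z decreasing in h: stable height)
.duz_dx <- function(x, theta, params) {
  ia <- 1 / params$alpha
  st <- sin(theta)
  params$v0 * (-3 * x^2 * 0.5 * (st + ia) +
                 2 * x * (9 * params$beta / 32) * (1 - 3 * st^2) +
                 (9 / 8) * ia)
}

#' Combined equilibrium height and orientation of a single squirmer
#'
#' Solves simultaneously the far-field orientation and vertical-velocity
#' fixed-point conditions for a squirmer under gravity above a wall, and
#' classifies the long-time state:
#' \describe{
#'   \item{`upright_floating`}{stable pair with `theta* = pi/2`.}
#'   \item{`tilted_swimming`}{stable pair on the tilted pusher branch
#'     `sin(theta*) = -2R/(3 beta h*)`.}
#'   \item{`oscillatory_none`}{strong pushers with no far-field pair: the
#'     tilted branch dives below the near-field boundary, where wall
#'     lubrication reorients the swimmer upright again, so oscillations are
#'     expected.}
#'   \item{`sunk_nearfield`}{no far-field pair and the swimmer settles to
#'     `R < h < 2R`, where the lubrication analysis applies.}
#' }
#' The upright/tilted boundary in the `(alpha, beta)` plane satisfies
#' `alpha = -4 (27 b^3 - 27 b - 16) / (27 b^3 + 64)` (see
#' [alpha_tilt_boundary()]).
#'
#' @param alpha gravity ratio `v0/vg`.
#' @param beta squirmer parameter.
#' @param params optional [squirmer_params()]; overrides `alpha`, `beta`.
#' @return An object of class `single_equilibrium`: list with `regime`,
#'   `h_star`, `theta_star`, `farfield_valid` (`h* > 2R`), and `equilibria`,
#'   a tibble of all stable pairs found (largest height flagged as the
#'   floating state).
#' @export
combined_equilibrium <- function(alpha, beta, params = NULL) {
  if (is.null(params)) params <- squirmer_params(beta = beta, alpha = alpha)
  alpha <- params$alpha
  beta <- params$beta
  R <- params$R
  ia <- 1 / alpha

  eq <- tibble::tibble(h = numeric(0), theta = numeric(0), branch = character(0))

  # upright branch: sin(theta) = 1; cubic in x = R/h
  up <- .real_roots_in(c(1 - ia, (9 / 8) * ia, -9 * beta / 16,
                         -0.5 * (1 + ia)), 0, 1)
  for (x in up) {
    h <- R / x
    height_stable <- .duz_dx(x, pi / 2, params) > 0
    orient_stable <- .farfield_dtheta_dtheta(h, pi / 2, params) < 0
    if (height_stable && orient_stable) {
      eq <- dplyr::bind_rows(eq, tibble::tibble(h = h, theta = pi / 2,
                                                branch = "upright"))
    }
  }

  # tilted pusher branch: sin(theta) = -2x/(3 beta), quartic in x
  if (beta < 0) {
    tl <- .real_roots_in(c(-ia, (9 / 8) * ia - 2 / (3 * beta), 9 * beta / 32,
                           -0.5 * ia, -1 / (24 * beta)), 0, 1)
    tl <- tl[tl <= -1.5 * beta + 1e-12]  # sin(theta) <= 1
    for (x in tl) {
      h <- R / x
      st <- -2 * x / (3 * beta)
      theta <- asin(st)
      height_stable <- .duz_dx(x, theta, params) > 0
      orient_stable <- .farfield_dtheta_dtheta(h, theta, params) < 0
      if (height_stable && orient_stable) {
        eq <- dplyr::bind_rows(eq, tibble::tibble(h = h, theta = theta,
                                                  branch = "tilted"))
      }
    }
  }

  if (nrow(eq) > 0) {
    eq <- dplyr::arrange(eq, dplyr::desc(.data$h))
    eq$floating <- seq_len(nrow(eq)) == 1
    regime <- if (eq$branch[1] == "upright") "upright_floating" else "tilted_swimming"
    out <- list(regime = regime, h_star = eq$h[1], theta_star = eq$theta[1],
                farfield_valid = eq$h[1] > 2 * R, equilibria = eq,
                alpha = alpha, beta = beta)
  } else {
    regime <- if (beta < -1) "oscillatory_none" else "sunk_nearfield"
    out <- list(regime = regime, h_star = NA_real_, theta_star = NA_real_,
                farfield_valid = FALSE, equilibria = eq,
                alpha = alpha, beta = beta)
  }
  class(out) <- "single_equilibrium"
  out
}

#' @export
print.single_equilibrium <- function(x, ...) {
  cat(sprintf("<single_equilibrium> alpha = %g, beta = %g: %s\n",
              x$alpha, x$beta, x$regime))
  if (!is.na(x$h_star)) {
    cat(sprintf("  h* = %.4f R, theta* = %.4f rad%s\n", x$h_star, x$theta_star,
                if (x$farfield_valid) "" else "  [h* <= 2R: outside far-field validity]"))
  }
  invisible(x)
}

#' @export
tidy.single_equilibrium <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta, regime = x$regime,
                 h_star = x$h_star, theta_star = x$theta_star,
                 farfield_valid = x$farfield_valid)
}

#' Upright/tilted boundary of the single-squirmer phase diagram
#'
#' The locus in the `(alpha, beta)` plane where the upright floating state of
#' a pusher gives way to tilted swimming:
#' `alpha = -4 (27 beta^3 - 27 beta - 16) / (27 beta^3 + 64)`.
#'
#' @param beta squirmer parameter (vectorised).
#' @return `alpha` on the boundary.
#' @export
alpha_tilt_boundary <- function(beta) {
  -4 * (27 * beta^3 - 27 * beta - 16) / (27 * beta^3 + 64)
}

#' Phase diagram of single-squirmer equilibrium states
#'
#' Classifies the long-time state of a single squirmer under gravity above a
#' wall on a grid of gravity ratio `alpha` and squirmer parameter `beta`.
#'
#' @param alpha,beta numeric grids.
#' @return Tibble (class `squirmer_phase_diagram`) with columns
#'   `alpha, beta, regime, h_star, theta_star`.
#' @export
phase_diagram <- function(alpha = seq(0.5, 2, by = 0.01),
                          beta = seq(-2, 2, by = 0.01)) {
  grid <- expand.grid(alpha = alpha, beta = beta)
  res <- purrr::map2(grid$alpha, grid$beta,
                     function(a, b) {
                       ce <- combined_equilibrium(a, b)
                       list(regime = ce$regime, h_star = ce$h_star,
                            theta_star = ce$theta_star)
                     })
  out <- tibble::tibble(alpha = grid$alpha, beta = grid$beta,
                        regime = purrr::map_chr(res, "regime"),
                        h_star = purrr::map_dbl(res, "h_star"),
                        theta_star = purrr::map_dbl(res, "theta_star"))
  class(out) <- c("squirmer_phase_diagram", class(out))
  out
}

#' Minimum pusher strength admitting a stable far-field equilibrium
#'
#' Scans `beta` upward and reports the smallest value for which any gravity
#' ratio in `alpha_grid` yields a stable far-field height-and-orientation
#' pair with `h* > R`. Far-field pusher equilibria exist only for weak
#' pushers; this locates the existence bound.
#'
#' @param alpha_grid,beta_grid numeric grids (defaults: `alpha` in
#'   `[0.5, 2]`, `beta` in `[-2, 0]`, step 0.005).
#' @return Smallest `beta` in `beta_grid` with a stable far-field pair.
#' @export
min_pusher_beta_farfield <- function(alpha_grid = seq(0.5, 2, by = 0.005),
                                     beta_grid = seq(-2, 0, by = 0.005)) {
  for (b in sort(beta_grid)) {
    for (a in alpha_grid) {
      ce <- combined_equilibrium(a, b)
      if (!is.na(ce$h_star)) return(b)
    }
  }
  NA_real_
}

#' Near-field wall-induced reorientation rate
#'
#' Lubrication-regime (`R < h < 2R`) angular rate of a squirmer above a
#' wall, `(3 v0 / 2R) cos(theta) (1 - beta sin(theta))`, with the logarithmic
#' gap correction dropped. The sign convention is fixed so that the known
#' stability structure holds: upright (`theta = pi/2`) is stable for
#' `beta < 1`; strong pullers (`beta > 1`) tilt to `arcsin(1/beta)`; strong
#' pushers (`beta < -1`) admit a stable downward state. Fixed points depend
#' only on `beta`, not on the gap.
#'
#' @param theta orientation angle from horizontal.
#' @param params a [squirmer_params()] object.
#' @return `dtheta/dt` (radians per time).
#' @export
nearfield_angular_velocity <- function(theta, params) {
  (3 * params$v0 / (2 * params$R)) * cos(theta) * (1 - params$beta * sin(theta))
}

# analytic d/dtheta of the near-field rate
.nearfield_drate_dtheta <- function(theta, beta, v0 = 1, R = 1) {
  -(3 * v0 / (2 * R)) * (sin(theta) * (1 - beta * sin(theta)) +
                           beta * cos(theta)^2)
}

#' Near-field orientation fixed points and stability
#'
#' @param beta squirmer parameter.
#' @return Tibble with `theta`, `stable`, `branch`
#'   (upright / downward / tilted).
#' @export
nearfield_fixed_points <- function(beta) {
  out <- tibble::tibble(theta = c(pi / 2, -pi / 2),
                        branch = c("upright", "downward"))
  if (abs(beta) > 1) {
    out <- dplyr::bind_rows(out, tibble::tibble(theta = asin(1 / beta),
                                                branch = "tilted"))
  }
  out$stable <- .nearfield_drate_dtheta(out$theta, beta) < 0
  out
}

#' Critical squirmer parameter for upright near-field stability
#'
#' The `beta` at which the upright fixed point of the near-field
#' reorientation rate changes stability, found as the root in `beta` of the
#' angular-rate derivative at `theta = pi/2`.
#'
#' @param interval search interval for `beta`.
#' @return Critical `beta` (analytically 1).
#' @export
nearfield_upright_threshold <- function(interval = c(-3, 3)) {
  uniroot(function(b) .nearfield_drate_dtheta(pi / 2, b),
          interval, tol = 1e-12)$root
}
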