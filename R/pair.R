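#' Symmetric two-squirmer configuration above a wall
#'
#' Mirror-symmetric in-plane pair: swimmer 1 at `(0, h, 0)` with orientation
#' `e1 = (cos(theta), sin(theta), 0)`, swimmer 2 at `(D, h, 0)` with
#' `e2 = (-cos(theta), sin(theta), 0)` (facing each other when tilted).
#' The wall is at `y = 0`.
#'
#' @param D centre-to-centre distance (radii).
#' @param h common height above the wall (radii).
#' @param theta common tilt from horizontal (radians).
#' @return A `pair_state` list with positions and orientations; carries a
#'   `farfield_valid` flag (`D > 2R` and `h > 2R`).
#' @export
pair_state <- function(D, h, theta) {
  if (D <= 0 || h <= 0) stop("D and h must be positive")
  structure(list(
    D = D, h = h, theta = theta,
    x1 = c(0, h, 0), x2 = c(D, h, 0),
    e1 = c(cos(theta), sin(theta), 0),
    e2 = c(-cos(theta), sin(theta), 0),
    farfield_valid = D > 2 && h > 2
  ), class = "pair_state")
}

# ambient flow and vorticity felt by a swimmer at `xs` with orientation `es`
# in the presence of the wall and one other swimmer (`xo`, `eo`)
.pair_ambient <- function(xs, es, xo, eo, params) {
  list(
    u_wall = squirmer_image_flow(xs, xs, es, params),
    u_direct = squirmer_flow(xs, xo, eo, params),
    u_image_other = squirmer_image_flow(xs, xo, eo, params),
    vorticity = flow_vorticity(xs, xo, eo, params) +
      squirmer_image_vorticity(xs, xs, es, params) +
      squirmer_image_vorticity(xs, xo, eo, params)
  )
}

#' Reorientation rate of a symmetric squirmer pair
#'
#' `dtheta/dt` of swimmer 1, equal to half the z-vorticity of the ambient
#' flow at its centre (the ambient flow being the direct flow of swimmer 2
#' plus both wall image systems). Reduces to the single-swimmer wall rate as
#' `D` grows.
#'
#' @param state a [pair_state()].
#' @param params a [squirmer_params()] object.
#' @return `dtheta/dt` (scalar).
#' @export
pair_angular_velocity <- function(state, params) {
  amb <- .pair_ambient(state$x1, state$e1, state$x2, state$e2, params)
  0.5 * amb$vorticity[3]
}

#' Translational velocity of a symmetric squirmer pair
#'
#' In-plane velocity of swimmer 1, decomposed into self-propulsion,
#' wall-corrected sedimentation, the swimmer's own wall image, the direct
#' flow of swimmer 2, and the wall image of swimmer 2. Each addend is
#' returned separately alongside the total.
#'
#' @inheritParams pair_angular_velocity
#' @return Named list of 3-vectors: `self`, `gravity`, `wall`, `direct`,
#'   `image_other`, `total`.
#' @export
pair_velocity <- function(state, params) {
  amb <- .pair_ambient(state$x1, state$e1, state$x2, state$e2, params)
  self <- params$v0 * state$e1
  gravity <- c(0, -sedimentation_speed(max(state$h, params$R), params), 0)
  total <- self + gravity + amb$u_wall + amb$u_direct + amb$u_image_other
  list(self = self, gravity = gravity, wall = amb$u_wall,
       direct = amb$u_direct, image_other = amb$u_image_other, total = total)
}

#' Short-range repulsion velocity
#'
#' Lateral repulsion preventing sphere overlap in encounter simulations,
#' `u_r = -v0 (e . ex) / (2 (D - 2R))` applied to swimmer 1 along x. It is
#' proportional to the lateral swimming speed, so it vanishes for upright
#' swimmers, and in the dynamics it maintains `D >= 2.5 R`.
#'
#' @inheritParams pair_angular_velocity
#' @return Scalar x-velocity for swimmer 1.
#' @export
repulsion_velocity <- function(state, params) {
  if (state$D <= 2 * params$R) stop("spheres in contact: D <= 2R")
  -params$v0 * sum(state$e1 * c(1, 0, 0)) / (2 * (state$D - 2 * params$R))
}

# one explicit-Euler step of the symmetric pair; D frozen when fix_D = TRUE
.pair_step <- function(state, params, dt, fix_D = FALSE, repulsion = !fix_D) {
  v <- pair_velocity(state, params)
  u <- v$total
  dth <- pair_angular_velocity(state, params)
  dD <- if (fix_D) 0 else -2 * (u[1] + if (repulsion) repulsion_velocity(state, params) else 0)
  h_new <- max(state$h + dt * u[2], params$R)
  pair_state(state$D + dt * dD, h_new, state$theta + dt * dth)
}

#' Stationary pair state at fixed separation
#'
#' Evolves the common height and tilt of a symmetric pair with the
#' separation `D` held fixed, starting from the single-swimmer equilibrium,
#' until both rates drop below `tol` for 100 consecutive steps.
#'
#' @param D fixed centre-to-centre distance (radii).
#' @param params a [squirmer_params()] object.
#' @param init optional starting `(h, theta)`; defaults to the
#'   single-swimmer equilibrium for `params`.
#' @param dt Euler time step.
#' @param tol stationarity tolerance on `|dh/dt|` and `|dtheta/dt|`.
#' @param t_max time budget; non-convergence within it raises a warning.
#' @return List `(h, theta, converged, t)`.
#' @export
relax_fixed_distance <- function(D, params, init = NULL, dt = 0.01,
                                 tol = 1e-8, t_max = 4000) {
  if (is.null(init)) {
    ce <- combined_equilibrium(params$alpha, params$beta, params)
    if (is.na(ce$h_star)) {
      stop("no single-swimmer far-field equilibrium to start from (regime ",
           ce$regime, ")")
    }
    init <- c(h = ce$h_star, theta = ce$theta_star)
  }
  r <- .pair_relax_cpp(D, init[["h"]], init[["theta"]], params$p, params$s,
                       params$v0, params$vg, params$R, dt, tol, t_max)
  if (r[3] == 0) {
    warning("relax_fixed_distance did not reach stationarity within t_max")
  }
  list(h = r[1], theta = r[2], converged = r[3] == 1, t = r[4])
}

#' Stationary pair states over a range of separations
#'
#' @param D_grid separations to relax at.
#' @inheritParams relax_fixed_distance
#' @return Tibble `(D, h, theta, converged)`.
#' @export
pair_fixed_distance_scan <- function(D_grid, params, dt = 0.01, tol = 1e-8,
                                     t_max = 4000) {
  ce <- combined_equilibrium(params$alpha, params$beta, params)
  if (is.na(ce$h_star)) stop("no single-swimmer equilibrium for these parameters")
  init <- c(h = ce$h_star, theta = ce$theta_star)
  res <- purrr::map(sort(D_grid, decreasing = TRUE), function(D) {
    r <- relax_fixed_distance(D, params, init = init, dt = dt, tol = tol,
                              t_max = t_max)
    # continue each relaxation from the previous (adjacent-D) solution
    init <<- c(h = r$h, theta = r$theta)
    tibble::tibble(D = D, h = r$h, theta = r$theta, converged = r$converged)
  })
  dplyr::arrange(dplyr::bind_rows(res), .data$D)
}

#' Dynamic encounter of two symmetric squirmers
#'
#' Time integration of the mirror-symmetric pair starting from the
#' single-swimmer equilibrium at separation `D0`. A short-range repulsion
#' keeps the centre separation above `2.5 R`. A run is classified `collide`
#' when `D` reaches the repulsion floor and stays there for 50 steps, and
#' `separate` otherwise.
#'
#' @param D0 initial separation (radii).
#' @param params a [squirmer_params()] object.
#' @param dt Euler time step (default `0.01 R/v0`).
#' @param t_max horizon.
#' @param record_every store every k-th step in the trajectory.
#' @return Object of class `pair_encounter`: list with `trajectory`
#'   (tibble `t, D, h, theta`), `outcome` (`"collide"` / `"separate"`), and
#'   the inputs.
#' @export
simulate_encounter <- function(D0, params, dt = 0.01, t_max = 400,
                               record_every = 10L) {
  ce <- combined_equilibrium(params$alpha, params$beta, params)
  if (is.na(ce$h_star)) stop("no single-swimmer equilibrium for these parameters")
  r <- .pair_encounter_cpp(D0, ce$h_star, ce$theta_star, params$p, params$s,
                           params$v0, params$vg, params$R, dt, t_max,
                           as.integer(record_every))
  traj <- r$trajectory
  colnames(traj) <- c("t", "D", "h", "theta")
  out <- list(trajectory = tibble::as_tibble(as.data.frame(traj)),
              outcome = if (r$collide) "collide" else "separate",
              D0 = D0, params = params, dt = dt)
  class(out) <- "pair_encounter"
  out
}

#' @export
print.pair_encounter <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("<pair_encounter> beta = %g, D0 = %g: %s (t = %g, D = %.3f, h = %.3f, theta = %.3f)\n",
              x$params$beta, x$D0, x$outcome, last$t, last$D, last$h, last$theta))
  invisible(x)
}

#' @export
tidy.pair_encounter <- function(x, ...) x$trajectory

#' @export
glance.pair_encounter <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  tibble::tibble(beta = x$params$beta, alpha = x$params$alpha, D0 = x$D0,
                 outcome = x$outcome, t_end = last$t, D_end = last$D,
                 h_end = last$h, theta_end = last$theta)
}

#' Critical separation between attraction and repulsion
#'
#' For upright-floating swimmers the fixed-distance equilibrium tilt crosses
#' `pi/2` at a separation `D_c`: closer pairs lean towards each other and
#' attract, farther pairs lean away and repel. Located by bisection on the
#' relaxed tilt. Returns `Inf` when the equilibrium tilt stays below `pi/2`
#' over the whole scan (no repulsive range, as for tilted pushers).
#'
#' @param params a [squirmer_params()] object.
#' @param D_range scan interval for the separation.
#' @param tol bisection tolerance on `D`.
#' @param relax_tol stationarity tolerance passed to
#'   [relax_fixed_distance()].
#' @return `D_c` (radii), possibly `Inf`.
#' @export
critical_distance <- function(params, D_range = c(3, 40), tol = 0.05,
                              relax_tol = 1e-8) {
  ce <- combined_equilibrium(params$alpha, params$beta, params)
  if (is.na(ce$h_star)) stop("no single-swimmer equilibrium for these parameters")
  init <- c(h = ce$h_star, theta = ce$theta_star)
  tilt <- function(D) relax_fixed_distance(D, params, init = init,
                                           tol = relax_tol)$theta - pi / 2
  lo <- D_range[1]; hi <- D_range[2]
  f_hi <- tilt(hi)
  if (f_hi < 0) return(Inf)
  f_lo <- tilt(lo)
  if (f_lo > 0) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (tilt(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
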