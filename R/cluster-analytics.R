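#' In-plane lubrication torque on a ring swimmer
#'
#' Azimuthal (about y) torque on swimmer `i` of a planar circle of `N`
#' squirmers, for azimuthal deviations `dphi` of itself and its two ring
#' neighbours:
#' \deqn{\Gamma_y = \frac{12}{5}\pi\mu R^2 v_0 (-\ln\epsilon)\Big\{
#'  [c^-_i(1+\beta s^-_i) - c^+_i(1+\beta s^+_i)]
#'  + \tfrac14[c^-_{i-1}(1+\beta s^-_{i-1}) - c^+_{i+1}(1+\beta s^+_{i+1})]
#'  \Big\}}
#' with `c^{+/-}_j = cos(pi/N +/- dphi_j)` and likewise for sines. It
#' vanishes for the exactly inward configuration and is odd under a global
#' sign flip of the deviations.
#'
#' @param dphi_prev,dphi_i,dphi_next azimuthal deviations of swimmers
#'   `i - 1`, `i`, `i + 1` (radians).
#' @param N ring size.
#' @param eps dimensionless neighbour gap.
#' @param params a [squirmer_params()] object.
#' @return Torque about y on swimmer `i` (scalar).
#' @export
planar_torque <- function(dphi_prev, dphi_i, dphi_next, N, eps, params) {
  .check_eps(eps)
  a <- pi / N
  b <- params$beta
  term <- function(ang, sign) cos(a + sign * ang) * (1 + b * sin(a + sign * ang))
  bracket <- (term(dphi_i, -1) - term(dphi_i, +1)) +
    0.25 * (term(dphi_prev, -1) - term(dphi_next, +1))
  (12 / 5) * pi * params$mu * params$R^2 * params$v0 * (-log(eps)) * bracket
}

#' Single-swimmer planar perturbation torque
#'
#' Closed-form reduction of [planar_torque()] when only swimmer `i` is
#' perturbed by `tau`:
#' `(24/5) pi mu R^2 v0 (-ln eps) sin(tau) (sin(pi/N) - beta cos(tau) cos(2 pi/N))`.
#'
#' @param tau azimuthal perturbation of the single swimmer.
#' @inheritParams planar_torque
#' @return Torque about y (scalar).
#' @export
planar_perturbation_torque <- function(tau, N, eps, params) {
  .check_eps(eps)
  (24 / 5) * pi * params$mu * params$R^2 * params$v0 * (-log(eps)) *
    sin(tau) * (sin(pi / N) - params$beta * cos(tau) * cos(2 * pi / N))
}

#' Two-dimensional azimuthal stability criterion for a circle
#'
#' The inward circle is azimuthally stable when the single-swimmer
#' perturbation torque is restoring, i.e.
#' `beta cos(2 pi/N) > sin(pi/N)`:
#' pushers with `beta < sin(pi/N)/cos(2 pi/N) < 0` for `N = 2, 3`; pullers
#' with `beta > sin(pi/N)/cos(2 pi/N) > 0` for `N >= 5`. Squares (`N = 4`)
#' are always unstable (`cos(pi/2) = 0`).
#'
#' @param N ring size.
#' @return List with `threshold` (`|beta|` above which the stable side is
#'   stable; `Inf` for `N = 4`), `beta_c` (signed critical value, `NA` for
#'   `N = 4`), and `side` (`"pusher"`, `"puller"`, or `"none"`).
#' @export
criterion_azimuthal_2d <- function(N) {
  if (N < 2) stop("N >= 2 required")
  c2 <- cos(2 * pi / N)
  if (abs(c2) < 1e-12) {
    return(list(threshold = Inf, beta_c = NA_real_, side = "none"))
  }
  beta_c <- sin(pi / N) / c2
  list(threshold = abs(beta_c), beta_c = beta_c,
       side = if (beta_c < 0) "pusher" else "puller")
}

#' Polar lubrication torques in a tilted circle (scalar component forms)
#'
#' Local-z torque components on ring swimmer `i` when all azimuthal
#' deviations vanish and swimmers are tilted by elevation angles `theta`:
#' the own-flow term
#' `(12/5) pi mu R^2 v0 (-ln eps) (1 + beta cos(theta_i) sin(pi/N)) sin(theta_i) sin(pi/N)`
#' per neighbour, and the neighbour-flow term with coefficient `3/5` and the
#' neighbour's angle. These are the conventional scalar reductions; the dynamic
#' simulations assemble the full vector torques instead, in which the
#' neighbour-flow term enters the local balance with opposite sign (see the
#' package vignette).
#'
#' @param theta_i tilt of swimmer `i`.
#' @param theta_nb tilt of one neighbour.
#' @param N ring size.
#' @param eps dimensionless neighbour gap.
#' @param params a [squirmer_params()] object.
#' @return Named vector: `own` (per neighbour) and `from_neighbour`
#'   components of the z-torque.
#' @export
polar_torques <- function(theta_i, theta_nb, N, eps, params) {
  .check_eps(eps)
  s <- sin(pi / N)
  pref <- pi * params$mu * params$R^2 * params$v0 * (-log(eps))
  own <- (12 / 5) * pref * (1 + params$beta * cos(theta_i) * s) * sin(theta_i) * s
  nb <- (3 / 5) * pref * (1 + params$beta * cos(theta_nb) * s) * sin(theta_nb) * s
  c(own = own, from_neighbour = nb)
}

#' Stable uniform polar angle of a bulk puller circle
#'
#' Under the uniform polar mode all swimmers tilt together; the equilibrium
#' elevation is `arccos(-1/(beta sin(pi/N)))` when `beta sin(pi/N) > 1` and
#' `pi` (fully outward/overturned) otherwise. Either way the swimmers end up
#' directed out of the cluster: bulk puller circles are always unstable.
#'
#' @param N ring size.
#' @param beta squirmer parameter (puller, `beta > 0`).
#' @return Equilibrium polar angle (radians).
#' @export
stable_polar_angle <- function(N, beta) {
  bs <- beta * sin(pi / N)
  if (bs > 1) acos(-1 / bs) else pi
}

#' Azimuthal criterion for uniformly tilted pusher dimers and trimers
#'
#' With every swimmer tilted by elevation `theta`, the planar criterion for
#' `N = 2, 3` becomes `|beta| cos(theta) > -sin(pi/N)/cos(2 pi/N)`; the
#' threshold diverges as the tilt approaches vertical.
#'
#' @param N 2 or 3.
#' @param theta common tilt (|theta| < pi/2).
#' @return Threshold on `|beta|`.
#' @export
criterion_tilted_azimuthal <- function(N, theta) {
  if (!N %in% c(2, 3)) stop("tilted azimuthal criterion applies to N = 2 or 3")
  if (abs(theta) >= pi / 2) stop("|theta| >= pi/2: polar mode already broken")
  (-sin(pi / N) / cos(2 * pi / N)) / cos(theta)
}

#' Equilibrium tilt of a circle above a wall
#'
#' Balance of the polar lubrication torques from ring neighbours against the
#' wall torque, for the radially inward circle above a bottom wall:
#' \deqn{\tfrac34 L \sin(\pi/N)\tan\theta^* [1 + \beta\cos\theta^* \sin(\pi/N)]
#'   = \beta\sin\theta^* - 1,}
#' with `L = ln(eps)/ln(h - 1)` comparing swimmer-swimmer and swimmer-wall
#' lubrication strengths. Solved by bracketed bisection on
#' `theta in (0, pi/2)`; roots are reported smallest first. No root means
#' the wall cannot hold the tilt below vertical (polar break-up). In the
#' wall-dominated limit `L -> 0` the root tends to `arcsin(1/beta)`
#' (requires `beta > 1`).
#'
#' @param N ring size.
#' @param beta squirmer parameter.
#' @param L gap-ratio parameter `ln(eps)/ln(h-1)`, positive.
#' @return Numeric vector of roots `theta*` in `(0, pi/2)` (empty if none).
#' @export
wall_tilt_equilibrium <- function(N, beta, L) {
  if (L < 0) stop("L must be non-negative")
  s <- sin(pi / N)
  f <- function(th) {
    0.75 * L * s * tan(th) * (1 + beta * cos(th) * s) - (beta * sin(th) - 1)
  }
  lo <- 1e-6
  hi <- pi / 2 - 1e-6
  grid <- seq(lo, hi, length.out = 2001)
  fv <- vapply(grid, f, numeric(1))
  roots <- numeric(0)
  sgn <- sign(fv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (k in idx) {
    r <- tryCatch(uniroot(f, c(grid[k], grid[k + 1]), tol = 1e-10)$root,
                  error = function(e) NA_real_)
    if (!is.na(r)) roots <- c(roots, r)
  }
  sort(roots)
}

#' Azimuthal stability of a puller circle touching the wall
#'
#' As the circle approaches contact with the wall the tilt is set by the
#' wall alone (`cos(theta*) = 1/beta`), and the azimuthal criterion becomes
#' `beta^2 - 1 = sin(pi/N)/cos(2 pi/N)`, giving
#' `beta_c = sqrt(1 + sin(pi/N)/cos(2 pi/N))`, which decreases to 1 for
#' large rings.
#'
#' @param N ring size (`N >= 5`).
#' @return Critical `beta` for pullers at wall contact.
#' @export
criterion_contact_azimuthal <- function(N) {
  if (N < 5) stop("contact azimuthal criterion applies to puller circles, N >= 5")
  sqrt(1 + sin(pi / N) / cos(2 * pi / N))
}

#' Polar stability of a confined puller circle
#'
#' Between two walls the polar mode alternates between neighbours; the
#' circle is stable against it when
#' `beta > 5 L sin(pi/N) / (8 - 5 L sin(pi/N)^2)` (positive denominator;
#' otherwise no `beta` stabilises the mode).
#'
#' @param N ring size.
#' @param L gap-ratio parameter.
#' @return Threshold `beta` (or `Inf` when the denominator is non-positive).
#' @export
criterion_confined_polar <- function(N, L) {
  s <- sin(pi / N)
  den <- 8 - 5 * L * s^2
  if (den <= 0) return(Inf)
  5 * L * s / den
}

#' All applicable closed-form stability criteria
#'
#' Convenience table of the analytic thresholds for a given ring size and,
#' when supplied, gap-ratio parameter `L`.
#'
#' @param N ring size.
#' @param L optional gap-ratio parameter for wall/confinement criteria.
#' @return Tibble with columns `criterion`, `threshold`, `stable_side`.
#' @export
stability_criteria <- function(N, L = NA_real_) {
  az <- criterion_azimuthal_2d(N)
  out <- tibble::tibble(
    criterion = "azimuthal_2d",
    threshold = az$beta_c,
    stable_side = switch(az$side, pusher = "beta below", puller = "beta above",
                         none = "always unstable")
  )
  if (N >= 5) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      criterion = "contact_azimuthal",
      threshold = criterion_contact_azimuthal(N),
      stable_side = "beta above"
    ))
  }
  if (!is.na(L)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      criterion = "confined_polar",
      threshold = criterion_confined_polar(N, L),
      stable_side = "beta above"
    ))
  }
  out
}

#' Numeric polar stability threshold of a bulk circle
#'
#' Linearises the full vector-torque orientation dynamics of a bulk circle
#' about the inward configuration, restricted to the polar subspace
#' (elevations `theta_i`, azimuthal deviations held at zero), and bisects
#' the squirmer parameter where the largest growth rate changes sign. For
#' pusher trimers this locates the strength above which the polar mode is
#' unstable; the linearisation gives `-2/sqrt(3)` (every eigenvalue carries
#' the common factor `1 + beta sin(pi/N)`).
#'
#' @param N ring size.
#' @param eps neighbour gap (the threshold does not depend on it).
#' @param interval bisection interval for `beta`.
#' @return Critical `beta` where the polar growth rate changes sign.
#' @export
polar_stability_threshold <- function(N, eps = 0.5, interval = c(-3, -0.1)) {
  growth <- function(beta) max(Re(eigen(.polar_jacobian(N, beta, eps),
                                        only.values = TRUE)$values))
  uniroot(function(b) growth(b), interval, tol = 1e-9)$root
}

# Jacobian of d(theta)/dt with respect to theta at the inward configuration
.polar_jacobian <- function(N, beta, eps) {
  cfg <- build_circle(N, eps)
  par <- squirmer_params(beta = beta)
  mob <- 1 / (8 * pi * par$mu * par$R^3)
  rate <- function(th) {
    ors <- cbind(cos(th) * cfg$inward[, 1], sin(th), cos(th) * cfg$inward[, 3])
    om <- cluster_torques(cfg, ors, par) * mob
    dedt_y <- om[, 3] * ors[, 1] - om[, 1] * ors[, 3]
    dedt_y / cos(th)
  }
  d <- 1e-6
  J <- matrix(0, N, N)
  for (j in seq_len(N)) {
    th <- rep(0, N); th[j] <- d
    thm <- rep(0, N); thm[j] <- -d
    J[, j] <- (rate(th) - rate(thm)) / (2 * d)
  }
  J
}
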