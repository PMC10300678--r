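#' Lubrication torque from a squirmer's own flow near a neighbour
#'
#' Leading-order (log-in-gap) viscous torque on swimmer 1 generated by its
#' own squirming flow in the presence of a rigid sphere at swimmer 2:
#' `(12/5) pi mu R^2 v0 (1 + beta (e1 . e12)) (-ln eps) (e12 x e1)`,
#' with `e12` the unit vector from centre 1 to centre 2 and `eps` the
#' dimensionless surface gap (gap / R, `0 < eps < 1`).
#'
#' @param e1 unit orientation of swimmer 1.
#' @param e12 unit vector from centre 1 to centre 2.
#' @param eps dimensionless gap between the sphere surfaces.
#' @param params a [squirmer_params()] object.
#' @return Torque 3-vector on swimmer 1.
#' @export
torque_own_flow <- function(e1, e12, eps, params) {
  .check_eps(eps)
  (12 / 5) * pi * params$mu * params$R^2 * params$v0 *
    (1 + params$beta * sum(e1 * e12)) * (-log(eps)) * .cross(e12, e1)
}

#' Lubrication torque from the neighbour's squirming flow
#'
#' Torque on swimmer 1 due to the activity of swimmer 2:
#' `(3/5) pi mu R^2 v0 (1 + beta (e2 . e21)) (-ln eps) (e21 x e2)`.
#' For identical squirmers this is one quarter of the torque the same flow
#' exerts back on swimmer 2 (the own-flow term above with labels swapped).
#'
#' @param e2 unit orientation of swimmer 2.
#' @param e21 unit vector from centre 2 to centre 1 (`-e12`).
#' @inheritParams torque_own_flow
#' @return Torque 3-vector on swimmer 1.
#' @export
torque_other_flow <- function(e2, e21, eps, params) {
  .check_eps(eps)
  (3 / 5) * pi * params$mu * params$R^2 * params$v0 *
    (1 + params$beta * sum(e2 * e21)) * (-log(eps)) * .cross(e21, e2)
}

#' Lubrication torque from a nearby wall
#'
#' Wall torque on a squirmer hovering at dimensionless gap `eps_wall`
#' (= `h/R - 1`), obtained from the sphere-sphere result by letting one
#' sphere become a plane (twice the own-flow coefficient):
#' `(24/5) pi mu R^2 v0 (1 + beta (e1 . ew)) (-ln eps) (ew x e1)`,
#' where `ew` is the unit vector from the swimmer towards the wall. For an
#' in-plane tilt `theta` above a bottom wall this reduces to
#' `(24/5) pi mu R^2 v0 (-ln eps) cos(theta) (1 - beta sin(theta)) ez`,
#' the same fixed-point structure as the near-field single-swimmer rate.
#'
#' @param e1 unit orientation of the squirmer.
#' @param eps_wall dimensionless wall gap in `(0, 1)`.
#' @param params a [squirmer_params()] object.
#' @param wall_normal unit normal of the wall pointing into the fluid
#'   (default bottom wall, `c(0, 1, 0)`).
#' @return Torque 3-vector.
#' @export
wall_torque <- function(e1, eps_wall, params, wall_normal = c(0, 1, 0)) {
  .check_eps(eps_wall)
  ew <- -wall_normal
  (24 / 5) * pi * params$mu * params$R^2 * params$v0 *
    (1 + params$beta * sum(e1 * ew)) * (-log(eps_wall)) * .cross(ew, e1)
}

.check_eps <- function(eps) {
  if (any(eps <= 0) || any(eps >= 1)) {
    stop("lubrication gap eps must satisfy 0 < eps < 1")
  }
  invisible(eps)
}

#' Preferred relative orientation of a near-contact squirmer pair
#'
#' Qualitative classification of the pair configuration favoured by the
#' lubrication torques: weak or neutral squirmers (`|beta| <= 1`) align
#' facing opposite directions; strong pushers (`beta < -1`) align regardless
#' of relative orientation; strong pullers (`beta > 1`) reorient parallel to
#' one another.
#'
#' @param beta squirmer parameter.
#' @return One of `"facing_opposite"`, `"aligned_any"`, `"parallel"`.
#' @export
preferred_pair_orientation <- function(beta) {
  if (beta < -1) "aligned_any" else if (beta > 1) "parallel" else "facing_opposite"
}
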