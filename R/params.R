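#' Physical parameters of a spherical squirmer
#'
#' Bundles the parameters of the two-mode squirmer model: the squirmer
#' parameter `beta` (ratio of the second to the first squirming mode,
#' `beta < 0` for pushers, `beta > 0` for pullers), the bulk swimming speed
#' `v0`, the sphere radius `R`, the gravity ratio `alpha = v0 / vg` (swimming
#' speed over bulk sedimentation speed), and the fluid viscosity `mu`.
#'
#' Derived quantities are attached: the stresslet (force dipole) strength
#' `p = -(3/4) beta v0 R^2`, the source-dipole strength `s = v0 R^3 / 2`,
#' the bulk sedimentation speed `vg = v0 / alpha`, and the squirming mode
#' amplitudes `B1 = 3 v0 / 2`, `B2 = beta * B1`.
#'
#' The default nondimensionalisation is `R = v0 = mu = 1`: lengths in sphere
#' radii, times in `R / v0`. `alpha = Inf` disables gravity (`vg = 0`).
#'
#' @param beta squirmer parameter (dimensionless). Default `-0.3`, a weak
#'   pusher typical of active-droplet experiments.
#' @param alpha gravity ratio `v0 / vg` (dimensionless, `> 0`); default
#'   `0.77`, the experimental value used throughout.
#' @param v0 bulk swimming speed (length/time).
#' @param R sphere radius (length).
#' @param mu dynamic viscosity (mass/length/time).
#'
#' @return An object of class `squirmer_params` (a named list with the
#'   fields above plus `p`, `s`, `vg`, `B1`, `B2`).
#' @examples
#' sp <- squirmer_params(beta = 1)
#' sp$p  # negative for pullers
#' @export
squirmer_params <- function(beta = -0.3, alpha = 0.77, v0 = 1, R = 1, mu = 1) {
  stopifnot(is.numeric(beta), length(beta) == 1, is.finite(beta))
  if (!(R > 0)) stop("R must be positive")
  if (!(v0 >= 0)) stop("v0 must be non-negative")
  if (!(mu > 0)) stop("mu must be positive")
  if (!(alpha > 0)) stop("alpha must be positive (use alpha = Inf for no gravity)")
  out <- list(
    beta = beta, alpha = alpha, v0 = v0, R = R, mu = mu,
    p = -0.75 * beta * v0 * R^2,
    s = v0 * R^3 / 2,
    vg = if (is.finite(alpha)) v0 / alpha else 0,
    B1 = 1.5 * v0,
    B2 = beta * 1.5 * v0
  )
  class(out) <- "squirmer_params"
  out
}

#' @export
print.squirmer_params <- function(x, ...) {
  kind <- if (x$beta < 0) "pusher" else if (x$beta > 0) "puller" else "neutral squirmer"
  cat(sprintf("<squirmer_params> %s: beta = %g, alpha = %g, v0 = %g, R = %g, mu = %g\n",
              kind, x$beta, x$alpha, x$v0, x$R, x$mu))
  cat(sprintf("  stresslet p = %g, source dipole s = %g, vg = %g\n", x$p, x$s, x$vg))
  invisible(x)
}

#' Far-field singularity strengths of a squirmer
#'
#' The slowest-decaying flow singularities of a two-mode squirmer: a
#' stresslet of strength `p = -(3/4) beta v0 R^2` and a source dipole of
#' strength `s = v0 R^3 / 2`, both directed along the swimming axis.
#' `sign(p) = -sign(beta)`: pushers (`beta < 0`) have `p > 0`.
#'
#' @param params a [squirmer_params()] object.
#' @return Named numeric vector `c(p = , s = )`.
#' @export
singularity_strengths <- function(params) {
  stopifnot(inherits(params, "squirmer_params"))
  c(p = params$p, s = params$s)
}

#' Prescribed tangential slip velocity on the squirmer surface
#'
#' Surface boundary condition of the two-mode squirmer at the surface point
#' `R * e_r`:
#' `u = (3/2) v0 (1 + beta e.e_r) ((e.e_r) e_r - e)`,
#' which is tangential to the sphere and vanishes at both poles.
#'
#' @param e unit swimming direction.
#' @param e_r unit radial direction of the surface point.
#' @param params a [squirmer_params()] object.
#' @return Slip velocity 3-vector.
#' @export
surface_slip <- function(e, e_r, params) {
  stopifnot(inherits(params, "squirmer_params"))
  if (!.is_unit(e) || !.is_unit(e_r)) stop("e and e_r must be unit vectors")
  ce <- sum(e * e_r)
  1.5 * params$v0 * (1 + params$beta * ce) * (ce * e_r - e)
}
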