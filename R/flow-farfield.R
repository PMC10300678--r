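#' Far-field flow of a squirmer
#'
#' Velocity at a field point `x` induced by a squirmer at `position` with
#' orientation `e`, represented by its two leading hydrodynamic
#' singularities:
#' `u(r) = -(p/r^2)(1 - 3 (e.rhat)^2) rhat - (s/r^3)(e - 3 (e.rhat) rhat)`,
#' with `r` measured from the squirmer centre. Decays as `1/r^2` for
#' `beta != 0` (stresslet-dominated) and `1/r^3` for neutral squirmers.
#'
#' @param x field point (3-vector).
#' @param position squirmer centre (3-vector).
#' @param e unit orientation.
#' @param params a [squirmer_params()] object.
#' @return Velocity 3-vector.
#' @export
squirmer_flow <- function(x, position, e, params) {
  r <- x - position
  rn <- sqrt(sum(r^2))
  if (rn == 0) stop("field point coincides with the singularity location")
  rh <- r / rn
  ce <- sum(e * rh)
  -(params$p / rn^2) * (1 - 3 * ce^2) * rh - (params$s / rn^3) * (e - 3 * ce * rh)
}

#' Vorticity of the far-field squirmer flow
#'
#' Analytic curl of [squirmer_flow()]. The source dipole is a potential-flow
#' gradient field, so only the stresslet contributes. For a swimmer at the
#' origin with `e = (cos(theta), sin(theta), 0)` evaluated at `(-D, 0, 0)`
#' the z-component is `6 p sin(theta) cos(theta) / D^3`.
#'
#' @inheritParams squirmer_flow
#' @return Vorticity 3-vector.
#' @export
flow_vorticity <- function(x, position, e, params) {
  r <- x - position
  if (sum(r^2) == 0) stop("field point coincides with the singularity location")
  params$p * .stresslet_free_curl(x[1], x[2], x[3],
                                  position[1], position[2], position[3],
                                  e[1], e[2], e[3])
}

#' Describe a single wall-bounded flow singularity
#'
#' @param kind `"stresslet"` or `"source_dipole"`.
#' @param strength scalar singularity strength (`p` or `s`).
#' @param location 3-vector, strictly above the wall (`y > 0`).
#' @param axis unit 3-vector.
#' @return A `singularity_config` list.
#' @export
singularity_config <- function(kind = c("stresslet", "source_dipole"),
                               strength, location, axis) {
  kind <- match.arg(kind)
  if (!.is_unit(axis)) stop("axis must be a unit vector")
  if (location[2] <= 0) stop("singularity must lie strictly above the wall (y > 0)")
  structure(list(kind = kind, strength = strength,
                 location = location, axis = .normalize(axis)),
            class = "singularity_config")
}

#' Wall image flow of a single singularity
#'
#' Velocity of the image system alone (no direct singularity flow) for a
#' stresslet or source dipole above a rigid no-slip wall at `y = 0` with
#' fluid in `y > 0`. The images are the source-position derivatives of the
#' classical stokeslet image system for a half space, so the combined direct
#' plus image flow vanishes identically on the wall.
#'
#' @param x field point in the closed upper half-space.
#' @param source a [singularity_config()].
#' @return Velocity 3-vector of the image flow.
#' @export
image_system_flow <- function(x, source) {
  stopifnot(inherits(source, "singularity_config"))
  loc <- source$location
  e <- source$axis
  f <- switch(source$kind,
              stresslet = .stresslet_image_u,
              source_dipole = .sdipole_image_u)
  source$strength * f(x[1], x[2], x[3], loc[1], loc[2], loc[3], e[1], e[2], e[3])
}

#' Wall image flow of a full squirmer (stresslet + source dipole)
#'
#' @inheritParams squirmer_flow
#' @return Velocity 3-vector of the combined image flow.
#' @export
squirmer_image_flow <- function(x, position, e, params) {
  if (position[2] <= 0) stop("squirmer must lie strictly above the wall (y > 0)")
  params$p * .stresslet_image_u(x[1], x[2], x[3],
                                position[1], position[2], position[3],
                                e[1], e[2], e[3]) +
    params$s * .sdipole_image_u(x[1], x[2], x[3],
                                position[1], position[2], position[3],
                                e[1], e[2], e[3])
}

#' Vorticity of the squirmer wall-image flow
#'
#' Analytic curl (with respect to the field point) of
#' [squirmer_image_flow()]. Evaluated at the squirmer's own centre this is
#' the wall-induced rotation source: its z-component for
#' `e = (cos(theta), sin(theta), 0)` at height `h` is
#' `-(6 p / 8 h^3) sin(theta) cos(theta) + (6 s / 8 h^4) cos(theta)`.
#'
#' @inheritParams squirmer_flow
#' @return Vorticity 3-vector.
#' @export
squirmer_image_vorticity <- function(x, position, e, params) {
  if (position[2] <= 0) stop("squirmer must lie strictly above the wall (y > 0)")
  params$p * .stresslet_image_curl(x[1], x[2], x[3],
                                   position[1], position[2], position[3],
                                   e[1], e[2], e[3]) +
    params$s * .sdipole_image_curl(x[1], x[2], x[3],
                                   position[1], position[2], position[3],
                                   e[1], e[2], e[3])
}

#' Evaluate the wall-bounded squirmer flow on a grid
#'
#' Direct plus image flow of a single squirmer above the wall, evaluated on
#' a rectangular grid, returned as a tibble suitable for CSV export or
#' plotting.
#'
#' @param position,e squirmer centre and unit orientation.
#' @param params a [squirmer_params()] object.
#' @param xlim,ylim numeric length-2 ranges (y clipped to the fluid side).
#' @param n grid points per side.
#' @param z the (constant) z-plane of the grid.
#' @return Tibble with columns `x, y, z, ux, uy, uz`.
#' @export
flow_field_grid <- function(position, e, params,
                            xlim = c(-5, 5), ylim = c(0, 6), n = 25, z = 0) {
  grid <- expand.grid(x = seq(xlim[1], xlim[2], length.out = n),
                      y = seq(max(ylim[1], 1e-9), ylim[2], length.out = n))
  u <- t(apply(grid, 1, function(g) {
    xp <- c(g[["x"]], g[["y"]], z)
    if (sum((xp - position)^2) < (0.05 * params$R)^2) return(c(NA_real_, NA_real_, NA_real_))
    squirmer_flow(xp, position, e, params) +
      squirmer_image_flow(xp, position, e, params)
  }))
  tibble::tibble(x = grid$x, y = grid$y, z = z,
                 ux = u[, 1], uy = u[, 2], uz = u[, 3])
}
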