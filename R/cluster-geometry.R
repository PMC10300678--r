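#' Cluster configurations of near-contact squirmers
#'
#' Generators for the cluster geometries whose orientation stability is
#' analysed: a ring of `N` squirmers (`build_circle`), a ring with a central
#' vertical squirmer (`build_filled_circle`), and compact "partial circle"
#' shapes filling a hexagonal template (`build_partial_circle`). All
#' geometries lie in the horizontal (x-z) plane at height `h` above the
#' bottom wall (y up); positions are fixed during the orientation dynamics.
#'
#' Neighbouring ring swimmers are separated by a surface gap `eps * R`, so
#' the ring radius is `R (2 + eps) / (2 sin(pi/N))`.
#'
#' @param N number of swimmers.
#' @param eps dimensionless gap between neighbouring sphere surfaces.
#' @param walls `"none"`, `"bottom"`, or `"both"`.
#' @param h height of the swimmer plane above the bottom wall (radii);
#'   required when walls are present. Wall gaps must stay in the
#'   lubrication range (`0 < h - R < R`).
#' @param wall_gap_top surface gap to the top wall when `walls = "both"`
#'   (radii); defaults to the bottom gap `h - R`.
#' @param R sphere radius.
#' @return A `cluster_config` object: list with `positions` (N x 3 matrix),
#'   `orientations` (N x 3), `inward` (N x 3 unit vectors towards the ring
#'   centre), and the geometry metadata.
#' @examples
#' cfg <- build_circle(6, eps = 0.5)
#' neighbour_pairs(cfg)
#' @name cluster_geometry
NULL

.new_cluster_config <- function(positions, orientations, inward, geometry,
                                N, eps, walls, h, wall_gap_top, R) {
  if (walls != "none") {
    if (is.na(h)) stop("h is required when walls are present")
    if (h - R <= 0 || h - R >= R) {
      stop("bottom wall gap h - R must lie in (0, R) for the lubrication model")
    }
  }
  if (walls == "both") {
    if (is.na(wall_gap_top)) wall_gap_top <- h - R
    if (wall_gap_top <= 0 || wall_gap_top >= R) {
      stop("top wall gap must lie in (0, R)")
    }
  } else {
    wall_gap_top <- NA_real_
  }
  d <- as.matrix(stats::dist(positions))
  diag(d) <- Inf
  if (any(d < (2 + eps) * R - 1e-9)) {
    stop("generated geometry violates the minimum centre spacing R(2 + eps)")
  }
  structure(list(positions = positions, orientations = orientations,
                 inward = inward, geometry = geometry, N = N, eps = eps,
                 walls = walls, h = h, wall_gap_top = wall_gap_top, R = R),
            class = "cluster_config")
}

#' @rdname cluster_geometry
#' @export
build_circle <- function(N, eps, walls = c("none", "bottom", "both"),
                         h = NA_real_, wall_gap_top = NA_real_, R = 1) {
  walls <- match.arg(walls)
  if (N < 2) stop("a circle needs N >= 2")
  if (eps <= 0) stop("eps must be positive")
  rc <- R * (2 + eps) / (2 * sin(pi / N))
  phi <- 2 * pi * (seq_len(N) - 1) / N
  y <- if (walls == "none") 0 else h
  positions <- cbind(rc * cos(phi), y, rc * sin(phi))
  inward <- cbind(-cos(phi), 0, -sin(phi))
  .new_cluster_config(positions, inward, inward, "circle", N, eps, walls,
                      h, wall_gap_top, R)
}

#' @rdname cluster_geometry
#' @param centre_up logical: central squirmer initially points up (`TRUE`)
#'   or down.
#' @export
build_filled_circle <- function(N, eps, walls = c("none", "bottom", "both"),
                                h = NA_real_, wall_gap_top = NA_real_, R = 1,
                                centre_up = TRUE) {
  walls <- match.arg(walls)
  if (N < 4) stop("a filled circle needs N >= 4 (ring of N - 1 plus centre)")
  if (eps <= 0) stop("eps must be positive")
  n_ring <- N - 1
  rc <- R * (2 + eps) / (2 * sin(pi / n_ring))
  if (rc < 2 * R) {
    stop("central squirmer would overlap the ring for N = ", N)
  }
  phi <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  y <- if (walls == "none") 0 else h
  positions <- rbind(cbind(rc * cos(phi), y, rc * sin(phi)), c(0, y, 0))
  inward <- rbind(cbind(-cos(phi), 0, -sin(phi)), c(0, 0, 0))
  orientations <- rbind(cbind(-cos(phi), 0, -sin(phi)),
                        c(0, if (centre_up) 1 else -1, 0))
  .new_cluster_config(positions, orientations, inward, "filled_circle", N,
                      eps, walls, h, wall_gap_top, R)
}

#' @rdname cluster_geometry
#' @details Partial circles fill a hexagonal template of centre spacing
#'   `R (2 + eps)`: two adjacent outer sites first, then compact growth
#'   (dimer, triangle, rhombus, trapezoid, ...) until the filled hexagon at
#'   `N = 7`. All swimmers initially point at the cluster barycentre; a
#'   swimmer sitting exactly at the barycentre points up.
#' @export
build_partial_circle <- function(N, eps, walls = c("none", "bottom", "both"),
                                 h = NA_real_, wall_gap_top = NA_real_, R = 1) {
  walls <- match.arg(walls)
  if (N < 2 || N > 7) stop("partial circles are defined for 2 <= N <= 7")
  if (eps <= 0) stop("eps must be positive")
  d <- R * (2 + eps)
  hexv <- function(k) d * c(cos(k * pi / 3), 0, sin(k * pi / 3))
  sites <- list(hexv(0), hexv(1), c(0, 0, 0), hexv(2), hexv(5), hexv(3),
                hexv(4))
  y <- if (walls == "none") 0 else h
  positions <- do.call(rbind, sites[seq_len(N)])
  positions[, 2] <- y
  bary <- colMeans(positions)
  orientations <- t(apply(positions, 1, function(xi) {
    v <- bary - xi
    if (sqrt(sum(v^2)) < 1e-9) c(0, 1, 0) else .normalize(v)
  }))
  # azimuthal reference: horizontal direction towards the barycentre; a
  # zero row marks a swimmer at the barycentre (no azimuthal window)
  inward <- t(apply(positions, 1, function(xi) {
    v <- (bary - xi) * c(1, 0, 1)
    if (sqrt(sum(v^2)) < 1e-9) c(0, 0, 0) else .normalize(v)
  }))
  .new_cluster_config(positions, orientations, inward, "partial_circle", N,
                      eps, walls, h, wall_gap_top, R)
}

#' @export
print.cluster_config <- function(x, ...) {
  cat(sprintf("<cluster_config> %s: N = %d, eps = %g, walls = %s%s\n",
              x$geometry, x$N, x$eps, x$walls,
              if (x$walls != "none") sprintf(", h = %g", x$h) else ""))
  invisible(x)
}

#' @export
tidy.cluster_config <- function(x, ...) {
  tibble::tibble(swimmer = seq_len(x$N),
                 x = x$positions[, 1], y = x$positions[, 2],
                 z = x$positions[, 3],
                 ex = x$orientations[, 1], ey = x$orientations[, 2],
                 ez = x$orientations[, 3])
}

#' Interacting near-contact pairs in a cluster
#'
#' All unordered swimmer pairs whose surface gap is below one radius; only
#' these interact through lubrication torques. Each pair carries its own
#' dimensionless gap.
#'
#' @param config a `cluster_config`.
#' @return Tibble with columns `i`, `j`, `dist` (centre distance) and `eps`
#'   (surface gap in radii).
#' @export
neighbour_pairs <- function(config) {
  stopifnot(inherits(config, "cluster_config"))
  R <- config$R
  d <- as.matrix(stats::dist(config$positions))
  idx <- which(upper.tri(d) & d < 3 * R, arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2],
                 dist = d[idx],
                 eps = d[idx] / R - 2)
}
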