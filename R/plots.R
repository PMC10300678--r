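#' Plot a single-squirmer phase diagram
#'
#' Regime map in the `(beta, alpha)` plane with the analytic upright/tilted
#' boundary overlaid.
#'
#' @param object a tibble from [phase_diagram()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.squirmer_phase_diagram <- function(object, ...) {
  betas <- sort(unique(object$beta))
  boundary <- tibble::tibble(beta = betas,
                             alpha = alpha_tilt_boundary(betas))
  boundary <- boundary[boundary$alpha >= min(object$alpha) &
                         boundary$alpha <= max(object$alpha), ]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta, y = .data$alpha)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$regime)) +
    ggplot2::geom_line(data = boundary, colour = "red", linewidth = 0.4) +
    ggplot2::labs(x = expression(beta), y = expression(alpha),
                  fill = "regime") +
    ggplot2::theme_minimal()
}

#' Plot a pair-encounter trajectory
#'
#' Separation, height and tilt against time for a [simulate_encounter()]
#' run.
#'
#' @param object a `pair_encounter`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pair_encounter <- function(object, ...) {
  long <- tidyr_pivot(object$trajectory)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "t (R/v0)", y = NULL,
                  subtitle = sprintf("beta = %g, D0 = %g: %s",
                                     object$params$beta, object$D0,
                                     object$outcome)) +
    ggplot2::theme_minimal()
}

# minimal long-format helper (avoids a tidyr dependency for one reshape)
tidyr_pivot <- function(traj) {
  dplyr::bind_rows(
    tibble::tibble(t = traj$t, quantity = "D", value = traj$D),
    tibble::tibble(t = traj$t, quantity = "h", value = traj$h),
    tibble::tibble(t = traj$t, quantity = "theta", value = traj$theta)
  )
}

#' Plot cluster angle trajectories
#'
#' Azimuthal deviations and elevations of every swimmer over time for a
#' recorded [simulate_cluster()] replicate.
#'
#' @param object a `cluster_stability` run with `record_every > 0`.
#' @param replicate which replicate to show.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cluster_stability <- function(object, replicate = 1L, ...) {
  traj <- object$replicates[[replicate]]$trajectory
  if (is.null(traj)) {
    stop("no trajectory recorded; rerun simulate_cluster() with record_every > 0")
  }
  N <- object$config$N
  t <- traj[, 1]
  rows <- list()
  for (i in seq_len(N)) {
    rows[[i]] <- tibble::tibble(t = t, swimmer = i, angle = "dphi",
                                value = traj[, 1 + i])
    rows[[N + i]] <- tibble::tibble(t = t, swimmer = i, angle = "theta",
                                    value = traj[, 1 + N + i])
  }
  long <- dplyr::bind_rows(rows)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     group = .data$swimmer)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~.data$angle, ncol = 1) +
    ggplot2::geom_hline(yintercept = pi / 2, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "t (R/v0)", y = "angle (rad)") +
    ggplot2::theme_minimal()
}

#' Quiver plot of the wall-bounded squirmer flow
#'
#' @param field tibble from [flow_field_grid()].
#' @param arrow_scale arrow length per unit speed.
#' @return A ggplot.
#' @export
plot_flow_field <- function(field, arrow_scale = 0.3) {
  f <- field[is.finite(field$ux), ]
  sp <- sqrt(f$ux^2 + f$uy^2)
  scl <- arrow_scale / stats::median(sp[sp > 0])
  ggplot2::ggplot(f, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + scl * .data$ux,
                                       yend = .data$y + scl * .data$uy),
                          arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm")),
                          alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (R)", y = "y (R)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
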