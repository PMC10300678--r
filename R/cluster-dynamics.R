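#' Simulation protocol for cluster orientation dynamics
#'
#' @param dt Euler time step, in `R/v0` units (default 0.01).
#' @param noise_eta standard deviation of the rotational white noise
#'   magnitude, in `v0` units (default `0.05 v0`; converted to an angular
#'   rate with `R = 1`).
#' @param t_max simulation horizon (default 1000 `R/v0`, several e-folding
#'   times of the weakest modes at the threshold-scan resolution).
#' @param n_replicates independent noise realisations per parameter point; a
#'   configuration is stable only if every replicate holds its windows for
#'   the whole horizon.
#' @param seed integer seed; replicate `k` uses a derived seed so it is
#'   reproducible in isolation.
#' @return A `simulation_protocol` list.
#' @export
simulation_protocol <- function(dt = 0.01, noise_eta = 0.05, t_max = 1000,
                                n_replicates = 3, seed = 1L) {
  stopifnot(dt > 0, noise_eta >= 0, t_max > 0, n_replicates >= 1)
  structure(list(dt = dt, noise_eta = noise_eta, t_max = t_max,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "simulation_protocol")
}

# deterministic per-replicate seed stream from one global seed
.replicate_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}

# wall gap bookkeeping: -ln(eps) factors per swimmer for each wall
.wall_logs <- function(config) {
  N <- config$N
  if (config$walls == "none") {
    return(list(mode = 0L, bottom = rep(0, N), top = rep(0, N)))
  }
  R <- config$R
  eps_b <- config$positions[, 2] / R - 1
  .check_eps(eps_b)
  if (config$walls == "bottom") {
    return(list(mode = 1L, bottom = -log(eps_b), top = rep(0, N)))
  }
  y_top <- config$h + R + config$wall_gap_top
  eps_t <- (y_top - config$positions[, 2]) / R - 1
  .check_eps(eps_t)
  list(mode = 2L, bottom = -log(eps_b), top = -log(eps_t))
}

#' Total lubrication torques on every swimmer (reference implementation)
#'
#' Pure-R assembly of the pairwise own-flow and neighbour-flow torques and
#' the wall torques acting on each swimmer of a cluster. This mirrors the
#' compiled kernel used by [simulate_cluster()] and exists for testing and
#' for single-step inspection.
#'
#' @param config a `cluster_config`.
#' @param orientations N x 3 matrix of unit orientations (defaults to the
#'   configuration's initial ones).
#' @param params a [squirmer_params()] object.
#' @return N x 3 matrix of torques.
#' @export
cluster_torques <- function(config, orientations = config$orientations,
                            params) {
  N <- config$N
  np <- neighbour_pairs(config)
  torques <- matrix(0, N, 3)
  for (m in seq_len(nrow(np))) {
    i <- np$i[m]; j <- np$j[m]; eps <- np$eps[m]
    eij <- .normalize(config$positions[j, ] - config$positions[i, ])
    torques[i, ] <- torques[i, ] +
      torque_own_flow(orientations[i, ], eij, eps, params) +
      torque_other_flow(orientations[j, ], -eij, eps, params)
    torques[j, ] <- torques[j, ] +
      torque_own_flow(orientations[j, ], -eij, eps, params) +
      torque_other_flow(orientations[i, ], eij, eps, params)
  }
  if (config$walls != "none") {
    for (i in seq_len(N)) {
      eps_b <- config$positions[i, 2] / config$R - 1
      torques[i, ] <- torques[i, ] +
        wall_torque(orientations[i, ], eps_b, params, wall_normal = c(0, 1, 0))
      if (config$walls == "both") {
        y_top <- config$h + config$R + config$wall_gap_top
        eps_t <- (y_top - config$positions[i, 2]) / config$R - 1
        torques[i, ] <- torques[i, ] +
          wall_torque(orientations[i, ], eps_t, params,
                      wall_normal = c(0, -1, 0))
      }
    }
  }
  torques
}

#' One orientation update step (reference implementation)
#'
#' Explicit Euler rotation of all orientation vectors under the total
#' lubrication torques (converted with the isolated-sphere rotational
#' mobility `1/(8 pi mu R^3)`) plus optional rotational noise, followed by
#' renormalisation.
#'
#' @inheritParams cluster_torques
#' @param protocol a [simulation_protocol()].
#' @param params a [squirmer_params()] object.
#' @param planar restrict rotation (and noise) to the azimuthal y-axis.
#' @return Updated N x 3 orientation matrix.
#' @export
step_orientations <- function(config, orientations, protocol, params,
                              planar = FALSE) {
  mob <- 1 / (8 * pi * params$mu * params$R^3)
  om <- cluster_torques(config, orientations, params) * mob
  if (protocol$noise_eta > 0) {
    for (i in seq_len(config$N)) {
      mag <- rnorm(1, 0, protocol$noise_eta)
      axis <- if (planar) c(0, 1, 0) else .normalize(rnorm(3))
      om[i, ] <- om[i, ] + mag * axis
    }
  }
  if (planar) om[, c(1, 3)] <- 0
  out <- orientations
  for (i in seq_len(config$N)) {
    v <- orientations[i, ] + protocol$dt * .cross(om[i, ], orientations[i, ])
    out[i, ] <- .normalize(v)
  }
  out
}

#' Noisy orientation dynamics and stability classification of a cluster
#'
#' Integrates the orientation dynamics of a cluster with frozen positions
#' under lubrication torques and rotational white noise, and classifies the
#' run. In planar (`"2d"`) mode rotations are restricted to the cluster
#' plane and the circle is stable if every azimuthal deviation satisfies
#' `dphi < pi/2 - pi/N` throughout; in `"3d"` mode the windows are
#' `dphi < pi/2` and `|theta| < pi/2`. The configuration is stable only if
#' every noise replicate holds its windows for the whole horizon. The
#' failure mode is attributed to whichever window broke first (`"mixed"` if
#' both broke within 10 steps).
#'
#' @param config a `cluster_config`.
#' @param beta squirmer parameter (or pass `params`).
#' @param protocol a [simulation_protocol()].
#' @param mode `"2d"` (planar) or `"3d"`.
#' @param params optional [squirmer_params()]; its `beta` wins.
#' @param record_every if positive, keep each replicate's angle trajectory
#'   at this step stride.
#' @return Object of class `cluster_stability`: `stable`, `mode` (`"none"`,
#'   `"azimuthal"`, `"polar"`, `"mixed"`), `time_to_break`, `max_dphi`,
#'   `max_theta`, per-replicate details, and inputs.
#' @export
simulate_cluster <- function(config, beta, protocol = simulation_protocol(),
                             mode = c("3d", "2d"), params = NULL,
                             record_every = 0L) {
  mode <- match.arg(mode)
  if (is.null(params)) params <- squirmer_params(beta = beta)
  beta <- params$beta
  np <- neighbour_pairs(config)
  wl <- .wall_logs(config)
  planar <- mode == "2d"
  # planar inward window pi/2 - pi/N (N >= 3); for a dimer any orientation
  # with a positive component towards the partner points "inward", so pi/2
  dphi_window <- if (planar && config$N >= 3) pi / 2 - pi / config$N else pi / 2
  n_steps <- ceiling(protocol$t_max / protocol$dt)

  reps <- vector("list", protocol$n_replicates)
  for (k in seq_len(protocol$n_replicates)) {
    set.seed(.replicate_seed(protocol$seed, k))
    res <- .cluster_run_cpp(config$positions, config$orientations,
                            cbind(np$i - 1L, np$j - 1L), -log(np$eps),
                            beta, wl$mode, wl$bottom, wl$top,
                            config$inward, protocol$dt, n_steps,
                            protocol$noise_eta, planar, dphi_window, pi / 2,
                            10L, as.integer(record_every))
    az <- res$az_break_step
    pol <- res$pol_break_step
    broke <- az >= 0 || pol >= 0
    mode_k <- if (!broke) {
      "none"
    } else if (az >= 0 && pol >= 0 && abs(az - pol) <= 10) {
      "mixed"
    } else if (pol >= 0 && (az < 0 || pol < az)) {
      "polar"
    } else {
      "azimuthal"
    }
    reps[[k]] <- list(stable = !broke, mode = mode_k,
                      time_to_break = if (broke) min(c(az, pol)[c(az, pol) >= 0]) * protocol$dt else NA_real_,
                      max_dphi = res$max_dphi, max_theta = res$max_theta,
                      seed = .replicate_seed(protocol$seed, k),
                      trajectory = res$trajectory,
                      orientations = res$orientations)
  }
  stable <- all(vapply(reps, `[[`, logical(1), "stable"))
  tb <- vapply(reps, function(r) r$time_to_break %||% NA_real_, numeric(1))
  first <- if (all(is.na(tb))) NA_integer_ else which.min(tb)
  out <- list(stable = stable,
              mode = if (stable) "none" else reps[[first]]$mode,
              time_to_break = if (stable) NA_real_ else tb[first],
              max_dphi = max(vapply(reps, `[[`, numeric(1), "max_dphi")),
              max_theta = max(vapply(reps, `[[`, numeric(1), "max_theta")),
              replicates = reps, beta = beta, config = config,
              protocol = protocol, sim_mode = mode)
  class(out) <- "cluster_stability"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cluster_stability <- function(x, ...) {
  cat(sprintf("<cluster_stability> %s N = %d, beta = %g, walls = %s (%s): %s%s\n",
              x$config$geometry, x$config$N, x$beta, x$config$walls,
              x$sim_mode,
              if (x$stable) "stable" else "unstable",
              if (x$stable) "" else sprintf(" (%s, t = %.2f)", x$mode,
                                            x$time_to_break)))
  invisible(x)
}

#' @export
tidy.cluster_stability <- function(x, ...) {
  tibble::tibble(
    replicate = seq_along(x$replicates),
    stable = vapply(x$replicates, `[[`, logical(1), "stable"),
    mode = vapply(x$replicates, `[[`, character(1), "mode"),
    time_to_break = vapply(x$replicates, function(r) r$time_to_break %||% NA_real_, numeric(1)),
    max_dphi = vapply(x$replicates, `[[`, numeric(1), "max_dphi"),
    max_theta = vapply(x$replicates, `[[`, numeric(1), "max_theta"),
    seed = vapply(x$replicates, `[[`, integer(1), "seed")
  )
}

#' @export
glance.cluster_stability <- function(x, ...) {
  tibble::tibble(geometry = x$config$geometry, N = x$config$N,
                 beta = x$beta, eps = x$config$eps, walls = x$config$walls,
                 sim_mode = x$sim_mode, stable = x$stable, mode = x$mode,
                 time_to_break = x$time_to_break, max_dphi = x$max_dphi,
                 max_theta = x$max_theta)
}

#' Bisect the critical squirmer parameter of a cluster
#'
#' Locates the stability threshold `beta_c` along `beta` by bisection at a
#' given resolution, after checking the scan endpoints to determine the
#' stable side. If both endpoints classify identically the scan table is
#' returned with `beta_c = NA` (no threshold inside the range).
#'
#' @param builder zero-argument function returning the `cluster_config`
#'   (geometry is beta-independent).
#' @param beta_range length-2 numeric scan interval.
#' @param protocol a [simulation_protocol()].
#' @param mode `"2d"` or `"3d"`.
#' @param resolution bisection resolution on `beta` (default 0.01).
#' @return Object of class `threshold_scan`: `beta_c`, `stable_side`
#'   (`"low"`/`"high"`), and `evaluations` (tibble of every run).
#' @export
threshold_scan <- function(builder, beta_range, protocol = simulation_protocol(),
                           mode = c("3d", "2d"), resolution = 0.01) {
  mode <- match.arg(mode)
  config <- builder()
  evals <- list()
  classify <- function(beta) {
    r <- simulate_cluster(config, beta, protocol, mode = mode)
    evals[[length(evals) + 1L]] <<- glance(r)
    r$stable
  }
  lo <- min(beta_range); hi <- max(beta_range)
  s_lo <- classify(lo); s_hi <- classify(hi)
  if (s_lo == s_hi) {
    return(structure(list(beta_c = NA_real_,
                          stable_side = if (s_lo) "all" else "none",
                          evaluations = dplyr::bind_rows(evals)),
                     class = "threshold_scan"))
  }
  stable_side <- if (s_lo) "low" else "high"
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (classify(mid) == s_lo) lo <- mid else hi <- mid
  }
  structure(list(beta_c = (lo + hi) / 2, stable_side = stable_side,
                 evaluations = dplyr::bind_rows(evals)),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan> beta_c = %s (stable side: %s, %d runs)\n",
              format(x$beta_c), x$stable_side, nrow(x$evaluations)))
  invisible(x)
}

#' @export
tidy.threshold_scan <- function(x, ...) x$evaluations

#' Stability boundary of wall-bound clusters in the gap-spacing plane
#'
#' For each swimmer spacing `eps`, bisects over the wall gap `h - R` for the
#' edge of the region where the cluster is stable for at least one `beta` in
#' `beta_scan` (clusters near a wall destabilise as the gap shrinks).
#'
#' @param N cluster size (circle geometry).
#' @param eps_grid spacings to probe.
#' @param beta_scan candidate squirmer parameters ("stable for some beta").
#' @param protocol a [simulation_protocol()].
#' @param gap_range bisection interval for the wall gap (radii).
#' @param resolution relative bisection resolution on the gap.
#' @return Tibble `(eps, gap, h)` of boundary points.
#' @export
stability_boundary <- function(N, eps_grid, beta_scan,
                               protocol = simulation_protocol(),
                               gap_range = c(0.02, 0.95), resolution = 0.02) {
  stable_any <- function(eps, gap) {
    cfg <- build_circle(N, eps, walls = "bottom", h = 1 + gap)
    for (b in beta_scan) {
      if (simulate_cluster(cfg, b, protocol, mode = "3d")$stable) return(TRUE)
    }
    FALSE
  }
  rows <- purrr::map(eps_grid, function(eps) {
    lo <- gap_range[1]; hi <- gap_range[2]
    if (!stable_any(eps, hi)) {
      return(tibble::tibble(eps = eps, gap = NA_real_, h = NA_real_))
    }
    if (stable_any(eps, lo)) {
      return(tibble::tibble(eps = eps, gap = lo, h = 1 + lo))
    }
    while (hi / lo > 1 + resolution) {
      mid <- sqrt(lo * hi)
      if (stable_any(eps, mid)) hi <- mid else lo <- mid
    }
    g <- sqrt(lo * hi)
    tibble::tibble(eps = eps, gap = g, h = 1 + g)
  })
  dplyr::bind_rows(rows)
}

#' Power-law exponent of a stability boundary
#'
#' Least-squares slope `gamma` of `ln(h)` against `ln(eps)` for boundary
#' samples, i.e. the exponent in `h = eps^gamma`. Pass the wall gap as `h`
#' to fit the gap-based definition.
#'
#' @param boundary data frame with columns `eps` and `h` (or the column
#'   named in `h_col`).
#' @param h_col column to use for the vertical coordinate.
#' @return List with `gamma`, `se`, and the fitted `lm` object.
#' @export
exponent_fit <- function(boundary, h_col = "h") {
  b <- boundary[is.finite(boundary[[h_col]]) & is.finite(boundary$eps), ]
  if (nrow(b) < 4) stop("need at least 4 finite boundary points")
  if (max(b$eps) / min(b$eps) < 3) {
    stop("boundary points must span a sufficient range in eps")
  }
  fit <- lm(log(b[[h_col]]) ~ log(b$eps))
  list(gamma = unname(coef(fit)[2]),
       se = suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2])),
       fit = fit)
}
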