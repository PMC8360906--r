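#' Synthetic-data generator configuration
#'
#' Parameters of the pseudo-experimental data generators, which emulate the
#' confocal-derived measurements consumed by the analysis: manually traced
#' apical polygons around a contractile cluster (with tracing noise as
#' isotropic vertex jitter), exponential-saturation laser-ablation recoil
#' traces with additive Gaussian noise, and Poisson division events with a
#' configurable angular bias toward the cluster. All generators are
#' deterministic functions of `master_seed`.
#'
#' @param true_increment fractional contractility increase used to generate
#'   the tracings (0.09 = 9 percent).
#' @param n_pseudo_embryos number of independent pseudo-embryos (seeds).
#' @param vertex_jitter_sigma tracing noise, as a fraction of the mean edge
#'   length.
#' @param n_cells,cluster_size tissue size and cluster cell count per
#'   pseudo-embryo.
#' @param lambda,gamma mechanical parameters of the generating simulation.
#' @param recoil list: `groups` (data.frame with `group, d0, D, k`),
#'   `sigma_frac` (noise sd as a fraction of D), `dt` (frame interval,
#'   seconds), `n_points` (post-ablation frames), `n_pre` (pre-ablation
#'   frames), `n_traces` (traces per group).
#' @param divisions list: `rate` (percent of cells dividing per minute),
#'   `kappa` (angular concentration toward the cluster; 0 = uniform),
#'   `n_cells`, `duration_min`, `in_plane_prob`, `cluster_radius` and
#'   `field_radius` (geometry of the synthetic field, in cell diameters).
#' @param master_seed integer master seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(true_increment = 0.09,
                             n_pseudo_embryos = 5,
                             vertex_jitter_sigma = 0.02,
                             n_cells = 400,
                             cluster_size = 19,
                             lambda = 0.259,
                             gamma = 0.172,
                             recoil = list(),
                             divisions = list(),
                             master_seed = 1) {
  rec <- utils::modifyList(list(
    groups = data.frame(group = c("cluster", "boundary", "wildtype"),
                        d0 = c(10, 10, 10), D = c(2, 1.5, 1),
                        k = c(0.1, 0.1, 0.1)),
    sigma_frac = 0.05, dt = 4, n_points = 30, n_pre = 3, n_traces = 10),
    recoil)
  div <- utils::modifyList(list(
    rate = 0.2, kappa = 4, n_cells = 100, duration_min = 30,
    in_plane_prob = 0.9, cluster_radius = 3, field_radius = 8),
    divisions)
  stopifnot(true_increment >= 0, vertex_jitter_sigma >= 0,
            rec$sigma_frac >= 0, div$rate >= 0, div$kappa >= 0)
  structure(list(true_increment = true_increment,
                 n_pseudo_embryos = as.integer(n_pseudo_embryos),
                 vertex_jitter_sigma = vertex_jitter_sigma,
                 n_cells = as.integer(n_cells),
                 cluster_size = as.integer(cluster_size),
                 lambda = lambda, gamma = gamma,
                 recoil = rec, divisions = div,
                 master_seed = as.integer(master_seed)),
            class = "synthetic_config")
}

# translate the tissue so the cluster centroid sits at the box centre
recenter_cluster <- function(tis) {
  cl <- which(tis$cluster)
  cen <- t(vapply(cl, function(i) colMeans(cell_polygon(tis, i)), numeric(2)))
  ref <- cen[1, ]
  cen <- sweep(minimage(sweep(cen, 2, ref), tis$box), 2, ref, FUN = "+")
  shift <- tis$box / 2 - colMeans(cen)
  tis$vertices <- wrap_box(sweep(tis$vertices, 2, shift, FUN = "+"), tis$box)
  tis
}

#' Generate synthetic cell tracings
#'
#' Runs the vertex-model pipeline (random tissue, relaxation, zero net
#' stress, central cluster at `true_increment`, re-relaxation) once per
#' pseudo-embryo with a distinct derived seed, recentres the cluster, adds
#' isotropic Gaussian jitter to every junction (shared junctions receive
#' the same jitter, as a tracing would), and exports all cell polygons in
#' the tracing-table dialect.
#'
#' @param config a [synthetic_config()].
#' @param verbose print per-embryo progress.
#' @return data.frame with columns `embryo_id, cell_id, vertex_order, x, y,
#'   is_cluster` and attribute `box` (the periodic box, needed for
#'   periodic-aware measurement of simulated tracings).
#' @export
synth_tracings <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  par1 <- mechanical_params(config$lambda, config$gamma,
                            cluster_increment = config$true_increment)
  rows <- list()
  box <- NULL
  for (e in seq_len(config$n_pseudo_embryos)) {
    seed_e <- derive_seed(config$master_seed, e)
    tis <- generate_tissue(config$n_cells, seed = seed_e)
    tis <- relax(tis, par1, tol = 1e-6)
    tis <- zero_net_stress(tis, mechanical_params(config$lambda,
                                                  config$gamma))
    tis <- apply_cluster(tis, par1, target_size = config$cluster_size)
    tis <- recenter_cluster(tis)
    jit <- config$vertex_jitter_sigma * mean_edge_length(tis)
    if (jit > 0) {
      noise <- with_seed(derive_seed(seed_e, 7L),
                         matrix(rnorm(length(tis$vertices), sd = jit),
                                ncol = 2))
      tis$vertices <- wrap_box(tis$vertices + noise, tis$box)
    }
    box <- tis$box
    for (ci in seq_along(tis$cells)) {
      p <- cell_polygon(tis, ci)
      rows[[length(rows) + 1L]] <- data.frame(
        embryo_id = e, cell_id = ci, vertex_order = seq_len(nrow(p)),
        x = p[, 1], y = p[, 2], is_cluster = tis$cluster[ci])
    }
    if (verbose) message(sprintf("pseudo-embryo %d/%d done", e,
                                 config$n_pseudo_embryos))
  }
  out <- do.call(rbind, rows)
  attr(out, "box") <- box
  out
}

#' Generate synthetic recoil traces
#'
#' Traces \eqn{d(t) = d_0 + D (1 - e^{-kt}) + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)} with \eqn{\sigma} =
#' `sigma_frac * D`, sampled every `dt` seconds (default 4 s, the confocal
#' frame interval), with `n_pre` pre-ablation frames at the baseline.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `trace_id, group, time_s, distance`.
#' @export
synth_recoil <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  rc <- config$recoil
  with_seed(derive_seed(config$master_seed, 101L), {
    rows <- list()
    tid <- 0L
    for (gi in seq_len(nrow(rc$groups))) {
      g <- rc$groups[gi, ]
      for (r in seq_len(rc$n_traces)) {
        tid <- tid + 1L
        t <- c(-(rc$n_pre:1) * rc$dt, (0:(rc$n_points - 1)) * rc$dt)
        mu <- g$d0 + g$D * (1 - exp(-g$k * pmax(t, 0)))
        d <- mu + rnorm(length(t), sd = rc$sigma_frac * abs(g$D))
        rows[[tid]] <- data.frame(trace_id = tid, group = g$group,
                                  time_s = t, distance = d)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate synthetic division events
#'
#' Division events at a Poisson-distributed count with mean
#' `rate/100 * n_cells * duration_min`, at uniform times; dividing-cell
#' centroids are placed uniformly in an annulus between the cluster edge and
#' the field edge, and in-plane daughter-separation axes are drawn
#' concentrated toward the cluster: the axis deviates from the
#' centroid-to-cluster direction by a wrapped-normal-like angle with
#' standard deviation \eqn{1/\sqrt{\kappa}} radians (`kappa = 0` gives a
#' uniform axis).
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `event_id, time_min, centroid_x,
#'   centroid_y, axis_x, axis_y, in_plane`, with attributes `boundary` (the
#'   cluster boundary polygon as segment list), `n_cells` and
#'   `duration_min`.
#' @export
synth_divisions <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  dv <- config$divisions
  with_seed(derive_seed(config$master_seed, 202L), {
    n_events <- rpois(1, dv$rate / 100 * dv$n_cells * dv$duration_min)
    r0 <- dv$cluster_radius
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    circle <- cbind(r0 * cos(th), r0 * sin(th))
    boundary <- lapply(seq_len(nrow(circle)), function(i) {
      rbind(circle[i, ], circle[if (i == nrow(circle)) 1L else i + 1L, ])
    })
    if (n_events == 0L) {
      out <- data.frame(event_id = integer(0), time_min = numeric(0),
                        centroid_x = numeric(0), centroid_y = numeric(0),
                        axis_x = numeric(0), axis_y = numeric(0),
                        in_plane = logical(0))
    } else {
      rad <- sqrt(runif(n_events, r0^2, dv$field_radius^2))
      phi <- runif(n_events, 0, 2 * pi)
      cx <- rad * cos(phi)
      cy <- rad * sin(phi)
      # reference direction: centroid toward the cluster (disc at origin)
      ref <- atan2(-cy, -cx)
      dev <- if (dv$kappa > 0) rnorm(n_events, 0, 1 / sqrt(dv$kappa))
      else runif(n_events, 0, pi)
      ax <- ref + dev
      out <- data.frame(event_id = seq_len(n_events),
                        time_min = sort(runif(n_events, 0, dv$duration_min)),
                        centroid_x = cx, centroid_y = cy,
                        axis_x = cos(ax), axis_y = sin(ax),
                        in_plane = runif(n_events) < dv$in_plane_prob)
    }
    attr(out, "boundary") <- boundary
    attr(out, "n_cells") <- dv$n_cells
    attr(out, "duration_min") <- dv$duration_min
    out
  })
}

#' Measure a division-event table
#'
#' Computes the in-plane cell division rate (CDR, percent per minute) and
#' the in-plane division orientations (CDO, degrees in [0, 90] relative to
#' the closest cluster edge) of a division-event table; out-of-plane events
#' are excluded from CDO and counted.
#'
#' @param events data.frame as from [synth_divisions()].
#' @param boundary cluster boundary segments (defaults to the `boundary`
#'   attribute of `events`).
#' @param n_cells,duration_min observation field; default from attributes.
#' @return list with `cdr`, `cdo_deg`, `n_out_of_plane`, `rose` (the 10-degree
#'   bin counts).
#' @export
division_metrics <- function(events, boundary = NULL, n_cells = NULL,
                             duration_min = NULL) {
  boundary <- boundary %||% attr(events, "boundary")
  n_cells <- n_cells %||% attr(events, "n_cells")
  duration_min <- duration_min %||% attr(events, "duration_min")
  inp <- events[events$in_plane, , drop = FALSE]
  cdo <- vapply(seq_len(nrow(inp)), function(i) {
    division_orientation(c(inp$axis_x[i], inp$axis_y[i]),
                         c(inp$centroid_x[i], inp$centroid_y[i]), boundary)
  }, numeric(1))
  list(cdr = division_rate(nrow(inp), n_cells, duration_min),
       cdo_deg = cdo,
       n_out_of_plane = sum(!events$in_plane),
       rose = rose_histogram(cdo))
}
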