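#' Relax a tissue to mechanical equilibrium
#'
#' Minimises the total mechanical energy over all vertex positions with a
#' quasi-Newton (L-BFGS-B) descent using the analytic gradient, until the
#' largest per-vertex gradient norm falls below `tol`. When enabled, T1
#' neighbour-exchange moves are applied whenever an edge falls below a
#' threshold length (`t1_threshold` times the current mean edge length, the
#' new edge reopening perpendicular at 1.5x the threshold), after which
#' relaxation continues.
#'
#' @param tis a [tissue()].
#' @param params a [mechanical_params()].
#' @param tol convergence tolerance on the maximum per-vertex gradient norm.
#' @param t1 logical; enable T1 topological moves.
#' @param t1_threshold edge-collapse threshold, in units of the current mean
#'   edge length.
#' @param max_restarts maximum optimizer restarts (plus T1 rounds).
#' @return The relaxed [tissue()], with attributes `converged` (logical),
#'   `grad_norm` (final max per-vertex gradient norm), `energy_trace`
#'   (energy at start and after each descent stage) and `n_t1` (number of T1
#'   moves applied). Non-convergence is reported via a warning carrying the
#'   final gradient norm.
#' @export
relax <- function(tis, params, tol = 1e-6, t1 = TRUE, t1_threshold = 0.05,
                  max_restarts = 12L) {
  trace <- total_energy(tis, params)
  n_t1 <- 0L
  max_t1 <- 200L
  gmax <- Inf
  restarts <- 0L
  repeat {
    csr <- tissue_csr(tis)
    fn <- function(x) .tissue_energy_cpp(x, csr$cell_vert, csr$cell_ptr,
                                         tis$box, params$lambda,
                                         params$gamma, tis$gamma_multiplier)
    gr <- function(x) .tissue_grad_cpp(x, csr$cell_vert, csr$cell_ptr,
                                       tis$box, params$lambda, params$gamma,
                                       tis$gamma_multiplier)
    res <- optim(tissue_par(tis), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = 50000L, factr = 1, pgtol = tol / 4,
                                lmm = 20L))
    tis <- tissue_set_par(tis, res$par)
    trace <- c(trace, res$value)
    g <- tissue_gradient(tis, params)
    gmax <- max(sqrt(rowSums(g^2)))
    if (t1 && n_t1 < max_t1) {
      swapped <- t1_pass(tis, t1_threshold)
      if (!is.null(swapped)) {
        tis <- swapped
        n_t1 <- n_t1 + 1L
        next
      }
    }
    if (gmax <= tol) break
    restarts <- restarts + 1L
    if (restarts >= max_restarts) break
  }
  if (gmax > tol)
    warning(sprintf("relaxation did not reach tol=%.2g (final gradient norm %.3g)",
                    tol, gmax))
  tis$vertices <- wrap_box(tis$vertices, tis$box)
  attr(tis, "converged") <- gmax <= tol
  attr(tis, "grad_norm") <- gmax
  attr(tis, "energy_trace") <- trace
  attr(tis, "n_t1") <- n_t1
  tis
}

# One T1 pass: find the shortest edge below threshold and swap it.
# Returns the updated tissue, or NULL if no edge qualifies.
t1_pass <- function(tis, t1_threshold) {
  from <- unlist(tis$cells, use.names = FALSE)
  to <- unlist(lapply(tis$cells, function(cc) c(cc[-1], cc[1])),
               use.names = FALSE)
  keep <- from < to
  from <- from[keep]; to <- to[keep]
  d <- minimage(tis$vertices[to, , drop = FALSE] -
                  tis$vertices[from, , drop = FALSE], tis$box)
  len <- sqrt(rowSums(d^2))
  thresh <- t1_threshold * mean(len)
  short <- which(len < thresh)
  if (!length(short)) return(NULL)
  for (e in short[order(len[short])]) {
    out <- t1_swap(tis, from[e], to[e], new_length = 1.5 * thresh)
    if (!is.null(out)) return(out)
  }
  NULL
}

# T1 neighbour exchange on edge (v1, v2). The two cells sharing the edge
# each lose one endpoint; the two cells meeting the edge only at v1 or v2
# gain the other endpoint; the edge reopens perpendicular about its
# midpoint. The combinatorial reconnection with positive areas and
# consistent shared edges is selected by validation among the small set of
# candidates. Returns NULL when the swap is not applicable.
t1_swap <- function(tis, v1, v2, new_length) {
  has1 <- vapply(tis$cells, function(cc) v1 %in% cc, logical(1))
  has2 <- vapply(tis$cells, function(cc) v2 %in% cc, logical(1))
  AB <- which(has1 & has2)
  C <- which(has1 & !has2)
  D <- which(!has1 & has2)
  if (length(AB) != 2L || length(C) != 1L || length(D) != 1L) return(NULL)
  if (any(lengths(tis$cells[AB]) <= 3L)) return(NULL)
  p1 <- tis$vertices[v1, ]
  p2 <- p1 + minimage(tis$vertices[v2, ] - p1, tis$box)
  m <- (p1 + p2) / 2
  u <- p2 - p1
  nu <- sqrt(sum(u^2))
  u <- if (nu > 1e-12) u / nu else c(1, 0)
  w <- c(-u[2], u[1])
  h <- new_length / 2
  drop_one <- function(cc, v) cc[cc != v]
  insert_pair <- function(cc, at, pair) {
    i <- which(cc == at)
    append(cc[-i], pair, after = i - 1L)
  }
  for (sgn in c(1, -1)) {
    cand <- tis
    cand$vertices[v1, ] <- wrap_box(m + sgn * h * w, tis$box)
    cand$vertices[v2, ] <- wrap_box(m - sgn * h * w, tis$box)
    for (keepA in list(c(v1, v2), c(v2, v1))) {
      for (ordC in list(c(v1, v2), c(v2, v1))) {
        for (ordD in list(c(v1, v2), c(v2, v1))) {
          cand2 <- cand
          cand2$cells[[AB[1]]] <- drop_one(tis$cells[[AB[1]]], keepA[2])
          cand2$cells[[AB[2]]] <- drop_one(tis$cells[[AB[2]]], keepA[1])
          cand2$cells[[C]] <- insert_pair(tis$cells[[C]], v1, ordC)
          cand2$cells[[D]] <- insert_pair(tis$cells[[D]], v2, ordD)
          if (isTRUE(validate_tissue(cand2, stop_on_error = FALSE)))
            return(cand2)
        }
      }
    }
  }
  NULL
}

#' Rescale the box to zero net tissue stress
#'
#' Isotropically rescales the periodic box (and all vertex positions),
#' re-relaxing at each trial scale, and bisects the scale factor until the
#' area-weighted mean [peff()] is within `ptol` of zero. This realises the
#' "zero net tissue stress" initial condition.
#'
#' @param tis a relaxed [tissue()].
#' @param params a [mechanical_params()].
#' @param ptol tolerance on the area-weighted mean Peff.
#' @param interval scan interval of box scale factors (relative to the input
#'   box). Tissues from [generate_tissue()] start near their zero-stress
#'   size, so the crossing lies close to 1.
#' @param tol relaxation tolerance passed to [relax()].
#' @return The rescaled, relaxed [tissue()] with `|mean Peff| <= ptol`.
#'   Errors if the mean stress does not change sign over `interval`,
#'   reporting the stress at both ends.
#' @export
zero_net_stress <- function(tis, params, ptol = 1e-4,
                            interval = c(0.8, 1.2), tol = 1e-6) {
  # warm-started evaluation: rescale the most recently relaxed state, so
  # consecutive trial scales are reached by continuation
  cur <- tis
  cur_s <- 1
  scale_relax <- function(s) {
    t2 <- cur
    t2$vertices <- t2$vertices * (s / cur_s)
    t2$box <- t2$box * (s / cur_s)
    t2 <- relax(t2, params, tol = tol)
    cur <<- t2
    cur_s <<- s
    list(tis = t2, p = mean_peff(t2, params))
  }
  # walk down from scale 1 toward the compressed end until the mean stress
  # changes sign (avoids relaxing deeply compressed states never needed)
  f1 <- scale_relax(min(1, interval[2]))
  if (abs(f1$p) <= ptol) return(f1$tis)
  if (f1$p > 0) {
    hi <- min(1, interval[2]); fhi <- f1
    lo <- hi; flo <- f1
    repeat {
      lo <- lo - 0.1
      if (lo < interval[1] - 1e-9)
        stop(sprintf("mean Peff does not cross zero in scale interval [%g, %g]: %.4g and %.4g",
                     interval[1], interval[2], flo$p, fhi$p))
      flo <- scale_relax(max(lo, interval[1]))
      if (abs(flo$p) <= ptol) return(flo$tis)
      if (flo$p < 0) break
      fhi <- flo; hi <- lo
    }
  } else {
    lo <- min(1, interval[2]); flo <- f1
    hi <- lo; fhi <- f1
    repeat {
      hi <- hi + 0.1
      if (hi > interval[2] + 1e-9)
        stop(sprintf("mean Peff does not cross zero in scale interval [%g, %g]: %.4g and %.4g",
                     interval[1], interval[2], flo$p, fhi$p))
      fhi <- scale_relax(min(hi, interval[2]))
      if (abs(fhi$p) <= ptol) return(fhi$tis)
      if (fhi$p > 0) break
      flo <- fhi; lo <- hi
    }
  }
  fm <- NULL
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    fm <- scale_relax(mid)
    if (abs(fm$p) <= ptol) return(fm$tis)
    if (fm$p < 0) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid; fhi <- fm
    }
  }
  stop(sprintf("zero-net-stress bisection did not converge (last mean Peff %.3g)",
               fm$p))
}

#' Flag a central contractile cluster and re-relax
#'
#' Flags the cell whose centroid is nearest the box centre, then adds
#' successive adjacency rings until at least `target_size` cells are
#' flagged. Flagged cells get contractility multiplier
#' `1 + params$cluster_increment`, and the tissue is re-relaxed (with T1
#' moves enabled).
#'
#' @param tis a zero-net-stress [tissue()].
#' @param params a [mechanical_params()]; its `cluster_increment` is applied.
#' @param target_size desired cluster cell count (must be < n_cells / 4).
#' @param tol relaxation tolerance.
#' @return The perturbed, relaxed [tissue()] with `cluster` flags set.
#' @export
apply_cluster <- function(tis, params, target_size = 19, tol = 1e-6) {
  nc <- length(tis$cells)
  if (target_size >= nc / 4)
    stop("`target_size` must be smaller than a quarter of the tissue")
  cen <- t(vapply(seq_len(nc),
                  function(i) colMeans(cell_polygon(tis, i)), numeric(2)))
  target <- tis$box / 2
  d <- minimage(sweep(cen, 2, target), tis$box)
  seed_cell <- which.min(rowSums(d^2))
  adj <- cell_adjacency(tis)
  flagged <- seed_cell
  while (length(flagged) < target_size) {
    nxt <- unique(c(flagged, unlist(adj[flagged], use.names = FALSE)))
    if (length(nxt) == length(flagged)) break
    flagged <- nxt
  }
  tis$cluster <- seq_len(nc) %in% flagged
  tis$gamma_multiplier <- ifelse(tis$cluster, 1 + params$cluster_increment, 1)
  relax(tis, params, tol = tol, t1 = TRUE)
}
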