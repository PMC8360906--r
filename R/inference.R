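ORIENTATION_CATEGORIES <- c("1-3", "4-6", "7+")

#' Orientation dataset grouped by distance category
#'
#' Container for cell shape-orientation angles (degrees, [0, 90]) grouped
#' into the three distance categories used throughout the analysis: cells
#' 1-3, 4-6 and 7+ cell rings from the cluster.
#'
#' @param angles_by_category named list with elements `"1-3"`, `"4-6"` and
#'   `"7+"`, each a numeric vector of angles in [0, 90] (may be empty).
#' @param source `"experiment"` or `"simulation"`.
#' @param metadata optional list (seeds, increments, counts, ...).
#' @return object of class `orientation_dataset`.
#' @export
orientation_dataset <- function(angles_by_category,
                                source = c("experiment", "simulation"),
                                metadata = list()) {
  source <- match.arg(source)
  miss <- setdiff(ORIENTATION_CATEGORIES, names(angles_by_category))
  if (length(miss))
    stop("missing distance category: ", paste(miss, collapse = ", "))
  angles_by_category <- angles_by_category[ORIENTATION_CATEGORIES]
  for (cat in ORIENTATION_CATEGORIES) {
    a <- angles_by_category[[cat]]
    a <- a[!is.na(a)]
    if (length(a) && (any(a < 0) || any(a > 90)))
      stop(sprintf("category %s: angle outside [0, 90]", cat))
    angles_by_category[[cat]] <- as.numeric(a)
  }
  structure(list(angles_by_category = angles_by_category, source = source,
                 metadata = metadata),
            class = "orientation_dataset")
}

#' @export
print.orientation_dataset <- function(x, ...) {
  n <- vapply(x$angles_by_category, length, integer(1))
  cat(sprintf("Orientation dataset (%s): n = %s\n", x$source,
              paste(sprintf("%s: %d", names(n), n), collapse = ", ")))
  invisible(x)
}

#' Pool per-cell measurements into an orientation dataset
#'
#' Collects the `orientation_to_cluster` angles of a per-cell metrics table
#' (from [measure_tissue()] or [measure_tracings()], possibly row-bound
#' across seeds or embryos) into the three distance categories, dropping
#' cells with undefined axes.
#'
#' @param metrics per-cell metrics data.frame with `ring_category` and
#'   `orientation_to_cluster` columns.
#' @param source `"experiment"` or `"simulation"`.
#' @param metadata optional list stored in the dataset.
#' @return an [orientation_dataset()].
#' @export
pool_orientations <- function(metrics, source, metadata = list()) {
  ang <- lapply(ORIENTATION_CATEGORIES, function(cat) {
    a <- metrics$orientation_to_cluster[!is.na(metrics$ring_category) &
                                          metrics$ring_category == cat]
    a[!is.na(a)]
  })
  names(ang) <- ORIENTATION_CATEGORIES
  orientation_dataset(ang, source, metadata)
}

#' Empirical cumulative distribution of orientation angles
#'
#' Right-continuous, non-decreasing step function from 0 to 1.
#'
#' @param angles non-empty numeric sample.
#' @return a `stats::ecdf` step function.
#' @export
orientation_ecdf <- function(angles) {
  if (!length(angles)) stop("empty sample")
  stats::ecdf(angles)
}

#' 1D Wasserstein distance between two samples
#'
#' First Wasserstein (earth mover's) distance between the empirical
#' distributions of two samples, computed exactly as the integral of the
#' absolute difference of their empirical CDFs. Symmetric, zero iff the
#' empirical distributions coincide, and satisfies the triangle inequality.
#'
#' @param a,b non-empty numeric samples (angles in degrees, here).
#' @return non-negative distance, in the units of the samples.
#' @export
wasserstein_1d <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  grid <- sort(unique(c(a, b)))
  if (length(grid) == 1L) return(0)
  x <- grid[-length(grid)]
  fa <- stats::ecdf(a)(x)
  fb <- stats::ecdf(b)(x)
  sum(abs(fa - fb) * diff(grid))
}

#' Summed Wasserstein distance over distance categories
#'
#' Sum of the per-category 1D Wasserstein distances between two orientation
#' datasets, over the categories 1-3, 4-6 and 7+. A category empty in both
#' datasets contributes zero (with a warning); a category empty in exactly
#' one is an error.
#'
#' @param sim,exp [orientation_dataset()] objects.
#' @return list with `total` and per-category `distances`.
#' @export
summed_distance <- function(sim, exp) {
  stopifnot(inherits(sim, "orientation_dataset"),
            inherits(exp, "orientation_dataset"))
  d <- setNames(numeric(3), ORIENTATION_CATEGORIES)
  for (cat in ORIENTATION_CATEGORIES) {
    sa <- sim$angles_by_category[[cat]]
    ea <- exp$angles_by_category[[cat]]
    if (!length(sa) && !length(ea)) {
      warning(sprintf("category %s empty in both datasets; contributes 0",
                      cat))
      d[cat] <- 0
    } else if (!length(sa) || !length(ea)) {
      stop(sprintf("category %s empty in %s dataset only", cat,
                   if (length(sa)) "the experimental" else "the simulated"))
    } else {
      d[cat] <- wasserstein_1d(sa, ea)
    }
  }
  list(total = sum(d), distances = d)
}

#' Grid search for the cluster contractility increment
#'
#' Re-runs the simulation pipeline (random tissue, relaxation, zero net
#' stress, central cluster, re-relaxation, shape measurement) for every
#' candidate contractility increment on `grid` and every seed, pools the
#' measured orientations across seeds within each distance category, and
#' scores each increment by the summed Wasserstein distance to the
#' experimental orientation dataset. The best increment minimises the summed
#' distance (ties broken toward the smaller increment).
#'
#' @param exp experimental [orientation_dataset()].
#' @param config simulation configuration, as from [run_config()]; uses
#'   `n_cells`, `cluster_size`, `lambda`, `gamma` and tolerances.
#' @param grid increments to scan (fractions, within [0, 0.20]).
#' @param seeds integer seeds; one simulated replicate per seed per
#'   increment (zero-stress base tissues are shared across increments).
#' @param base_tissues optional pre-built list of zero-net-stress tissues,
#'   one per seed (as produced by [base_tissue()]), to avoid rebuilding.
#' @param verbose print progress.
#' @return object of class `sweep_result`: data.frame `table` with columns
#'   `increment, d_13, d_46, d_7plus, d_total, valid`, plus `best_increment`.
#' @export
contractility_sweep <- function(exp, config = run_config(),
                                grid = seq(0, 0.20, by = 0.01),
                                seeds = 1:5, base_tissues = NULL,
                                verbose = FALSE) {
  stopifnot(inherits(exp, "orientation_dataset"), length(seeds) >= 1L)
  if (any(grid < 0 | grid > 0.20 + 1e-12))
    stop("`grid` must lie within [0, 0.20]")
  grid <- sort(grid)
  if (is.null(base_tissues))
    base_tissues <- lapply(seeds, function(s) base_tissue(config, s))
  tab <- data.frame(increment = grid, d_13 = NA_real_, d_46 = NA_real_,
                    d_7plus = NA_real_, d_total = NA_real_, valid = FALSE)
  for (i in seq_along(grid)) {
    res <- tryCatch({
      par_i <- mechanical_params(config$lambda, config$gamma,
                                 cluster_increment = grid[i])
      metrics <- lapply(base_tissues, function(bt) {
        t2 <- apply_cluster(bt, par_i, target_size = config$cluster_size,
                            tol = config$relax_tol)
        measure_tissue(t2, par_i)
      })
      sim <- pool_orientations(do.call(rbind, metrics), "simulation",
                               metadata = list(increment = grid[i],
                                               seeds = seeds))
      summed_distance(sim, exp)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("grid point %.3g failed: %s", grid[i],
                      conditionMessage(res)))
    } else {
      tab$d_13[i] <- res$distances[["1-3"]]
      tab$d_46[i] <- res$distances[["4-6"]]
      tab$d_7plus[i] <- res$distances[["7+"]]
      tab$d_total[i] <- res$total
      tab$valid[i] <- TRUE
    }
    if (verbose)
      message(sprintf("increment %.2f: summed distance %.4g", grid[i],
                      tab$d_total[i]))
  }
  if (!any(tab$valid)) stop("every grid point failed")
  best <- tab$increment[tab$valid][which.min(tab$d_total[tab$valid])]
  structure(list(table = tab, best_increment = best,
                 seeds = seeds, n_seeds = length(seeds)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Contractility sweep over %d increments (%d seeds each)\n",
              nrow(x$table), x$n_seeds))
  cat(sprintf("  best increment: %.2f (%.0f%% contractility increase)\n",
              x$best_increment, 100 * x$best_increment))
  cat(sprintf("  summed Wasserstein distance at best: %.4g degrees\n",
              min(x$table$d_total[x$table$valid])))
  invisible(x)
}

#' Build a relaxed, zero-net-stress base tissue
#'
#' Convenience wrapper: [generate_tissue()], [relax()] and
#' [zero_net_stress()] under one configuration.
#'
#' @param config configuration list, as from [run_config()].
#' @param seed integer seed for the random tissue.
#' @return a relaxed [tissue()] with area-weighted mean Peff within
#'   tolerance of zero.
#' @export
base_tissue <- function(config = run_config(), seed = 1) {
  par0 <- mechanical_params(config$lambda, config$gamma)
  tis <- generate_tissue(config$n_cells, seed = seed)
  tis <- relax(tis, par0, tol = config$relax_tol)
  zero_net_stress(tis, par0, ptol = config$peff_tol, tol = config$relax_tol)
}
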