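#' Polygon centroid (vertex mean)
#'
#' Arithmetic mean of the vertex (tricellular junction) positions,
#' \eqn{C = (1/n)\sum_i R_i}. This is the centroid convention used by the
#' shape tensor, not the area centroid.
#'
#' @param polygon numeric matrix (n x 2) of vertex coordinates.
#' @return numeric length-2 centroid.
#' @export
poly_centroid <- function(polygon) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2L, nrow(polygon) >= 3L)
  colMeans(polygon)
}

#' Cell shape tensor
#'
#' Second-moment tensor of the junction positions about the centroid,
#' \eqn{S = (1/n) \sum_i (R_i - C) \otimes (R_i - C)}. Symmetric positive
#' semi-definite and rotation-equivariant; its principal eigenvector is the
#' cell's long axis.
#'
#' @inheritParams poly_centroid
#' @return symmetric 2 x 2 matrix.
#' @export
shape_tensor <- function(polygon) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2L, nrow(polygon) >= 3L)
  q <- sweep(polygon, 2, colMeans(polygon))
  crossprod(q) / nrow(polygon)
}

#' Principal axis of cell shape
#'
#' Orientation of the eigenvector of the principal (largest) eigenvalue of
#' the shape tensor, as an angle in degrees in [0, 180) (an axis and its
#' opposite are identified). Near-isotropic cells, where the eigenvalue gap
#' is below `tol` relative to the largest eigenvalue, are flagged undefined.
#'
#' @param S symmetric 2 x 2 shape tensor.
#' @param tol relative eigen-gap tolerance below which the axis is undefined.
#' @return list with `angle_deg` (in [0, 180), `NA` when undefined) and
#'   `defined` (logical).
#' @export
principal_axis <- function(S, tol = 1e-6) {
  S <- as.matrix(S)
  stopifnot(all(dim(S) == 2L))
  tr <- S[1, 1] + S[2, 2]
  gap2 <- (S[1, 1] - S[2, 2])^2 + 4 * S[1, 2]^2
  gap <- sqrt(max(gap2, 0))
  lmax <- (tr + gap) / 2
  if (lmax <= 0 || gap <= tol * lmax)
    return(list(angle_deg = NA_real_, defined = FALSE))
  ang <- rad2deg(0.5 * atan2(2 * S[1, 2], S[1, 1] - S[2, 2]))
  list(angle_deg = ang %% 180, defined = TRUE)
}

#' Cell circularity
#'
#' Ratio of the smaller over the larger eigenvalue of the shape tensor,
#' in (0, 1]; a perfect circle gives 1. Scale invariant.
#'
#' @inheritParams principal_axis
#' @return single numeric in (0, 1].
#' @export
circularity <- function(S) {
  S <- as.matrix(S)
  stopifnot(all(dim(S) == 2L))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) stop("degenerate (zero) shape tensor")
  max(min(ev) / max(ev), 0)
}

#' Ring (graph) distance to the cluster
#'
#' Breadth-first distance on the cell-adjacency graph (cells sharing an
#' edge) from the nearest cluster cell. Cluster cells have ring 0; the
#' distance categories used throughout the analysis are `"1-3"`, `"4-6"` and
#' `"7+"` cells from the cluster.
#'
#' @param adjacency list; `adjacency[[i]]` holds the neighbours of cell `i`.
#' @param cluster_flags logical per-cell cluster indicator.
#' @return integer vector of ring distances (`NA` for unreachable cells).
#' @seealso [ring_category()]
#' @export
ring_distance <- function(adjacency, cluster_flags) {
  n <- length(adjacency)
  stopifnot(length(cluster_flags) == n)
  if (!any(cluster_flags)) stop("no cluster cells flagged")
  ring <- rep(NA_integer_, n)
  frontier <- which(cluster_flags)
  ring[frontier] <- 0L
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adjacency[frontier], use.names = FALSE))
    nxt <- nxt[is.na(ring[nxt])]
    ring[nxt] <- d
    frontier <- nxt
  }
  ring
}

#' @rdname ring_distance
#' @param ring integer ring distances.
#' @return `ring_category` returns a character vector (`"cluster"`, `"1-3"`,
#'   `"4-6"`, `"7+"`).
#' @export
ring_category <- function(ring) {
  out <- rep(NA_character_, length(ring))
  out[ring == 0L] <- "cluster"
  out[ring >= 1L & ring <= 3L] <- "1-3"
  out[ring >= 4L & ring <= 6L] <- "4-6"
  out[ring >= 7L] <- "7+"
  out
}

# nearest point on segment ab to point p, with optional periodic min-image
point_segment_nearest <- function(p, a, b, box = NULL) {
  if (!is.null(box)) {
    a <- p + minimage(a - p, box)
    b <- a + minimage(b - a, box)
  }
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
  t <- min(max(t, 0), 1)
  a + t * ab
}

# reference vector from a point to the nearest point on a set of segments
reference_to_boundary <- function(p, segments, box = NULL) {
  best <- NULL
  bestd <- Inf
  for (s in segments) {
    q <- point_segment_nearest(p, s[1, ], s[2, ], box)
    d2 <- sum((q - p)^2)
    if (d2 < bestd) {
      bestd <- d2
      best <- q
    }
  }
  best - p
}

# centroid of a boundary-segment set, periodic-aware (the cluster is compact
# relative to the box, so unwrapping about the first endpoint is valid)
boundary_centroid <- function(segments, box = NULL) {
  pts <- do.call(rbind, segments)
  ref <- pts[1, ]
  if (!is.null(box))
    pts <- sweep(minimage(sweep(pts, 2, ref), box), 2, ref, FUN = "+")
  colMeans(pts)
}

# acute angle (degrees, [0,90]) between an undirected axis given as an angle
# in degrees and a reference vector
fold_acute <- function(axis_deg, ref) {
  phi <- rad2deg(atan2(ref[2], ref[1]))
  d <- abs((axis_deg - phi) %% 180)
  min(d, 180 - d)
}

#' Shape orientation relative to the cluster
#'
#' Acute angle, in degrees in [0, 90], between a cell's principal shape axis
#' and a reference line toward the cluster. 0 means the long axis points at
#' the cluster, 90 that it runs parallel to the cluster boundary direction.
#'
#' Two reference conventions are available: `"centroid"` (default) takes the
#' line from the cell centroid to the cluster centroid; `"boundary"` the
#' line to the nearest point on the cluster's outer boundary. The centroid
#' convention is the calibrated default: in a mechanically unperturbed
#' tissue the nearest-boundary reference of cluster-adjacent cells falls on
#' one of their own edges, which correlates with the cell's short axis and
#' biases the null distribution tangentially, whereas the centroid reference
#' leaves it uniform.
#'
#' @param centroids numeric matrix (n x 2) of cell centroids.
#' @param axis_deg principal-axis angles in degrees ([0, 180) or `NA` when
#'   undefined; undefined axes yield `NA` and are counted by the caller).
#' @param boundary list of 2 x 2 segment matrices (cluster outer boundary).
#' @param box optional periodic box for minimum-image geometry.
#' @param reference `"centroid"` or `"boundary"` (see Details).
#' @return numeric vector of angles in [0, 90] (`NA` where the axis is
#'   undefined).
#' @export
orientation_to_cluster <- function(centroids, axis_deg, boundary,
                                   box = NULL,
                                   reference = c("centroid", "boundary")) {
  reference <- match.arg(reference)
  centroids <- matrix(centroids, ncol = 2)
  ccen <- if (reference == "centroid") boundary_centroid(boundary, box)
  vapply(seq_len(nrow(centroids)), function(i) {
    if (is.na(axis_deg[i])) return(NA_real_)
    r <- if (reference == "centroid")
      minimage(ccen - centroids[i, ], box)
    else reference_to_boundary(centroids[i, ], boundary, box)
    fold_acute(axis_deg[i], r)
  }, numeric(1))
}

#' Division orientation relative to the cluster
#'
#' Acute angle, in degrees in [0, 90], between the anaphase daughter-nuclei
#' separation axis and the line from the cell centroid to the closest point
#' on the cluster boundary. The axis is undirected: an axis and its negation
#' give the same angle.
#'
#' @param axis numeric length-2 daughter-separation direction (need not be
#'   normalised).
#' @param centroid numeric length-2 dividing-cell centroid.
#' @param boundary list of 2 x 2 segment matrices.
#' @param box optional periodic box.
#' @return angle in degrees in [0, 90].
#' @export
division_orientation <- function(axis, centroid, boundary, box = NULL) {
  stopifnot(length(axis) == 2L, length(centroid) == 2L)
  n <- sqrt(sum(axis^2))
  if (n <= 0) stop("zero-length division axis")
  fold_acute(rad2deg(atan2(axis[2], axis[1])),
             reference_to_boundary(centroid, boundary, box))
}

#' Cell division rate
#'
#' Percentage of cells dividing per minute:
#' `100 * n_divisions / (n_cells * duration_min)`.
#'
#' @param n_divisions number of in-plane division events observed.
#' @param n_cells number of cells observed.
#' @param duration_min observation duration in minutes.
#' @return rate in percent per minute.
#' @export
division_rate <- function(n_divisions, n_cells, duration_min) {
  if (any(n_cells <= 0)) stop("`n_cells` must be positive")
  if (any(duration_min <= 0)) stop("`duration_min` must be positive")
  100 * n_divisions / (n_cells * duration_min)
}

#' Rose-histogram binning of orientation angles
#'
#' Counts angles in nine 10-degree bins over [0, 90]: right-open bins
#' [0,10), ..., [70,80), with the final bin [80,90] closed so that 90
#' degrees is included.
#'
#' @param angles numeric angles in degrees, all in [0, 90].
#' @return integer vector of 9 bin counts (named by bin).
#' @export
rose_histogram <- function(angles) {
  if (length(angles)) {
    bad <- which(!is.finite(angles) | angles < 0 | angles > 90)
    if (length(bad))
      stop(sprintf("angle out of [0, 90]: %s at position %d",
                   format(angles[bad[1]]), bad[1]))
  }
  counts <- tabulate(pmin(floor(angles / 10) + 1L, 9L), nbins = 9L)
  names(counts) <- paste0("[", seq(0, 80, 10), ",", seq(10, 90, 10),
                          c(rep(")", 8), "]"))
  counts
}

#' Plot a rose histogram
#'
#' Quarter-circle fan plot of 10-degree orientation bins, radius
#' proportional to count.
#'
#' @param counts 9 bin counts, as returned by [rose_histogram()].
#' @param col fill colour.
#' @param main plot title.
#' @return `counts`, invisibly.
#' @export
plot_rose <- function(counts, col = "#7A4F9E88", main = "") {
  stopifnot(length(counts) == 9L)
  r <- sqrt(counts / max(counts, 1))
  graphics::plot(NA, xlim = c(0, 1.05), ylim = c(0, 1.05), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  for (i in seq_len(9L)) {
    th <- deg2rad(seq((i - 1) * 10, i * 10, length.out = 16))
    graphics::polygon(c(0, r[i] * cos(th)), c(0, r[i] * sin(th)),
                      col = col, border = "grey30")
  }
  for (f in c(0.5, 1))
    graphics::lines(f * cos(deg2rad(0:90)), f * sin(deg2rad(0:90)),
                    col = "grey80", lty = 3)
  graphics::text(1.04 * cos(deg2rad(c(0, 45, 90))),
                 1.04 * sin(deg2rad(c(0, 45, 90))),
                 c("0", "45", "90"), cex = 0.8)
  invisible(counts)
}

# ---- whole-tissue / whole-tracing measurement ------------------------------

#' Measure per-cell shape and stress metrics of a simulated tissue
#'
#' Computes, for every cell: area, perimeter, Peff, centroid, circularity,
#' principal-axis angle, ring distance to the cluster, distance category and
#' shape orientation relative to the cluster boundary (periodic-aware).
#'
#' @param tis a [tissue()] with cluster cells flagged.
#' @param params a [mechanical_params()].
#' @param eigen_tol relative eigen-gap tolerance for [principal_axis()].
#' @param reference orientation reference convention, see
#'   [orientation_to_cluster()].
#' @return data.frame, one row per cell, with attribute
#'   `n_axis_undefined` counting cells excluded from orientation.
#' @export
measure_tissue <- function(tis, params, eigen_tol = 1e-6,
                           reference = c("centroid", "boundary")) {
  reference <- match.arg(reference)
  nc <- length(tis$cells)
  g <- cell_geometry(tis)
  p <- peff(g$area, g$perimeter, params, tis$gamma_multiplier)
  polys <- lapply(seq_len(nc), function(i) cell_polygon(tis, i))
  cen <- t(vapply(polys, poly_centroid, numeric(2)))
  S <- lapply(polys, shape_tensor)
  ax <- lapply(S, principal_axis, tol = eigen_tol)
  angle <- vapply(ax, `[[`, numeric(1), "angle_deg")
  circ <- vapply(S, circularity, numeric(1))
  ring <- ring_distance(cell_adjacency(tis), tis$cluster)
  orient <- rep(NA_real_, nc)
  if (any(tis$cluster) && !all(tis$cluster)) {
    bnd <- cluster_boundary_segments(tis)
    nonc <- which(!tis$cluster)
    orient[nonc] <- orientation_to_cluster(cen[nonc, , drop = FALSE],
                                           angle[nonc], bnd, tis$box,
                                           reference = reference)
  }
  out <- data.frame(
    cell_id = seq_len(nc),
    is_cluster = tis$cluster,
    ring = ring,
    ring_category = ring_category(ring),
    area = g$area,
    perimeter = g$perimeter,
    peff = p,
    centroid_x = cen[, 1],
    centroid_y = cen[, 2],
    circularity = circ,
    principal_angle = angle,
    orientation_to_cluster = orient,
    stringsAsFactors = FALSE)
  attr(out, "n_axis_undefined") <- sum(is.na(angle))
  out
}

# simple-polygon test (no two non-adjacent edges intersect)
polygon_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  inter <- function(i, j) {
    d1 <- seg[i, 3:4] - seg[i, 1:2]
    d2 <- seg[j, 3:4] - seg[j, 1:2]
    r <- seg[j, 1:2] - seg[i, 1:2]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(FALSE)
    t <- (r[1] * d2[2] - r[2] * d2[1]) / den
    u <- (r[1] * d1[2] - r[2] * d1[1]) / den
    t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next
      if (inter(i, j)) return(FALSE)
    }
  }
  TRUE
}

#' Measure traced cell polygons
#'
#' Computes the shape metrics of [measure_tissue()] (minus the mechanical
#' ones) from a cell-tracing table: one row per traced junction, columns
#' `embryo_id, cell_id, vertex_order, x, y, is_cluster`. Cell adjacency is
#' reconstructed from shared junction coordinates, ring distances by
#' breadth-first search, and orientations are measured against the cluster's
#' outer boundary.
#'
#' @param tracings data.frame in the tracing-table dialect (or a CSV path).
#' @param box optional periodic box `c(Lx, Ly)` when the tracing derives
#'   from a periodic simulation; junction identity and reference vectors
#'   then use minimum-image geometry.
#' @param eigen_tol relative eigen-gap tolerance for [principal_axis()].
#' @param reference orientation reference convention, see
#'   [orientation_to_cluster()].
#' @return data.frame with one row per cell (columns `embryo_id, cell_id,
#'   is_cluster, ring, ring_category, circularity, principal_angle,
#'   orientation_to_cluster`), with attribute `n_axis_undefined`.
#' @export
measure_tracings <- function(tracings, box = NULL, eigen_tol = 1e-6,
                             reference = c("centroid", "boundary")) {
  reference <- match.arg(reference)
  if (is.character(tracings)) {
    path <- tracings
    tracings <- read.csv(path, stringsAsFactors = FALSE)
    if (is.null(box)) box <- attr(tracings, "box")
  }
  box <- box %||% attr(tracings, "box")
  need <- c("embryo_id", "cell_id", "vertex_order", "x", "y", "is_cluster")
  miss <- setdiff(need, names(tracings))
  if (length(miss))
    stop("tracing table lacks column(s): ", paste(miss, collapse = ", "))
  out <- list()
  n_undef <- 0L
  for (emb in unique(tracings$embryo_id)) {
    te <- tracings[tracings$embryo_id == emb, ]
    ids <- unique(te$cell_id)
    polys <- lapply(ids, function(cid) {
      pp <- te[te$cell_id == cid, ]
      pp <- pp[order(pp$vertex_order), ]
      as.matrix(pp[, c("x", "y")])
    })
    is_cl <- vapply(ids, function(cid)
      te$is_cluster[te$cell_id == cid][1] %in% c(TRUE, 1), logical(1))
    for (k in seq_along(polys)) {
      if (nrow(polys[[k]]) < 3L)
        stop(sprintf("embryo %s cell %s: fewer than 3 vertices", emb, ids[k]))
      if (!polygon_is_simple(polys[[k]]))
        stop(sprintf("embryo %s cell %s: self-intersecting polygon",
                     emb, ids[k]))
      # normalise to anticlockwise
      n <- nrow(polys[[k]]); i2 <- c(2:n, 1)
      a <- sum(polys[[k]][, 1] * polys[[k]][i2, 2] -
                 polys[[k]][i2, 1] * polys[[k]][, 2]) / 2
      if (a < 0) polys[[k]] <- polys[[k]][n:1, , drop = FALSE]
    }
    # junction keys: canonical (wrapped) coordinates rounded
    keys <- lapply(polys, function(p) {
      q <- if (is.null(box)) p else wrap_box(p, box)
      paste(round(q[, 1], 4), round(q[, 2], 4))
    })
    nc <- length(ids)
    adj <- vector("list", nc)
    # two cells are adjacent when they share a traced junction pair (edge)
    edge_keys <- lapply(keys, function(k) {
      paste(pmin(k, c(k[-1], k[1])), pmax(k, c(k[-1], k[1])), sep = "|")
    })
    edge_owner <- split(rep.int(seq_len(nc), lengths(edge_keys)),
                        unlist(edge_keys, use.names = FALSE))
    for (own in edge_owner) {
      own <- unique(own)
      if (length(own) == 2L) {
        adj[[own[1]]] <- c(adj[[own[1]]], own[2])
        adj[[own[2]]] <- c(adj[[own[2]]], own[1])
      }
    }
    adj <- lapply(adj, unique)
    if (!any(is_cl))
      stop(sprintf("embryo %s: no cluster cells flagged", emb))
    ring <- ring_distance(adj, is_cl)
    # cluster outer boundary: cluster-cell edges not shared with another
    # cluster cell
    segs <- list()
    for (ci in which(is_cl)) {
      p <- polys[[ci]]
      ek <- edge_keys[[ci]]
      for (t in seq_along(ek)) {
        others <- setdiff(unique(edge_owner[[ek[t]]]), ci)
        if (!length(others) || !any(is_cl[others])) {
          t2 <- if (t == length(ek)) 1L else t + 1L
          segs[[length(segs) + 1L]] <- rbind(p[t, ], p[t2, ])
        }
      }
    }
    S <- lapply(polys, shape_tensor)
    ax <- lapply(S, principal_axis, tol = eigen_tol)
    angle <- vapply(ax, `[[`, numeric(1), "angle_deg")
    n_undef <- n_undef + sum(is.na(angle) & !is_cl)
    cen <- t(vapply(polys, poly_centroid, numeric(2)))
    orient <- rep(NA_real_, nc)
    nonc <- which(!is_cl)
    orient[nonc] <- orientation_to_cluster(cen[nonc, , drop = FALSE],
                                           angle[nonc], segs, box,
                                           reference = reference)
    out[[length(out) + 1L]] <- data.frame(
      embryo_id = emb, cell_id = ids, is_cluster = is_cl, ring = ring,
      ring_category = ring_category(ring),
      circularity = vapply(S, circularity, numeric(1)),
      principal_angle = angle, orientation_to_cluster = orient,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "n_axis_undefined") <- n_undef
  res
}
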