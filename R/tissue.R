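#' Tissue mesh objects
#'
#' A `tissue` is a planar polygonal tiling of a periodic rectangular box:
#' vertex positions (tricellular junctions), cells as anticlockwise
#' vertex-index cycles, a per-cell cortical-contractility multiplier and a
#' per-cell cluster flag.
#'
#' @param vertices numeric matrix (n_vertices x 2), coordinates in box units.
#' @param cells list of integer vectors; each an anticlockwise cycle of
#'   vertex indices (>= 3 per cell).
#' @param box numeric length-2, periodic box dimensions `c(Lx, Ly)`.
#' @param gamma_multiplier per-cell factor on gamma (1 = wild type).
#' @param cluster logical per-cell cluster flag.
#' @return An object of class `tissue`.
#' @seealso [generate_tissue()], [validate_tissue()]
#' @export
tissue <- function(vertices, cells, box,
                   gamma_multiplier = rep(1, length(cells)),
                   cluster = rep(FALSE, length(cells))) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  stopifnot(ncol(vertices) == 2L, length(box) == 2L, all(box > 0))
  cells <- lapply(cells, as.integer)
  stopifnot(length(gamma_multiplier) == length(cells),
            length(cluster) == length(cells))
  structure(
    list(vertices = vertices, cells = cells, box = as.numeric(box),
         gamma_multiplier = as.numeric(gamma_multiplier),
         cluster = as.logical(cluster)),
    class = "tissue")
}

#' @export
print.tissue <- function(x, ...) {
  cat(sprintf("Vertex-model tissue: %d cells, %d vertices, box %.3g x %.3g\n",
              length(x$cells), nrow(x$vertices), x$box[1], x$box[2]))
  if (any(x$cluster))
    cat(sprintf("  cluster: %d cells, gamma multiplier %.4g\n",
                sum(x$cluster), max(x$gamma_multiplier)))
  invisible(x)
}

# CSR layout used by the C++ kernels (0-based indices)
tissue_csr <- function(tis) {
  nv <- lengths(tis$cells)
  list(cell_vert = as.integer(unlist(tis$cells, use.names = FALSE) - 1L),
       cell_ptr = as.integer(c(0L, cumsum(nv))))
}

# flat interleaved coordinate vector (x1,y1,x2,y2,...) for the optimizer
tissue_par <- function(tis) as.vector(t(tis$vertices))

tissue_set_par <- function(tis, par) {
  tis$vertices <- matrix(par, ncol = 2, byrow = TRUE)
  tis
}

#' Per-cell area and perimeter
#'
#' Shoelace area and edge-length sum with periodic (minimum-image)
#' unwrapping, so cells straddling the box boundary are measured correctly.
#'
#' @param tis a [tissue()].
#' @param cell_index optional integer; if given, return geometry of that cell
#'   only (list with `area` and `perimeter`), else vectors for all cells.
#' @return list with numeric `area` and `perimeter`.
#' @export
cell_geometry <- function(tis, cell_index = NULL) {
  csr <- tissue_csr(tis)
  g <- .tissue_geom_cpp(tissue_par(tis), csr$cell_vert, csr$cell_ptr, tis$box)
  bad <- which(g$area <= 0)
  if (length(bad))
    stop("non-positive area (self-intersecting or clockwise cell): cell ",
         paste(bad, collapse = ", "))
  if (is.null(cell_index)) g
  else list(area = g$area[cell_index], perimeter = g$perimeter[cell_index])
}

#' Unwrapped polygon of one cell
#'
#' Reconstructs the cell's vertex coordinates as a connected polygon by
#' accumulating minimum-image displacements from its first vertex.
#'
#' @param tis a [tissue()].
#' @param cell_index cell number.
#' @return numeric matrix (n x 2), anticlockwise.
#' @export
cell_polygon <- function(tis, cell_index) {
  idx <- tis$cells[[cell_index]]
  p <- tis$vertices[idx, , drop = FALSE]
  if (nrow(p) > 1) {
    d <- minimage(p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE],
                  tis$box)
    p[-1, 1] <- p[1, 1] + cumsum(d[, 1])
    p[-1, 2] <- p[1, 2] + cumsum(d[, 2])
  }
  p
}

#' Validate tissue invariants
#'
#' Checks that every cell has at least 3 vertices, every vertex belongs to
#' exactly three cells (tricellular junctions), every shared edge appears in
#' exactly two cells with opposite traversal, and all periodically unwrapped
#' cell areas are positive.
#'
#' @param tis a [tissue()].
#' @param stop_on_error if `FALSE`, return `FALSE` instead of raising.
#' @return `TRUE` invisibly (or `FALSE` when `stop_on_error = FALSE`).
#' @export
validate_tissue <- function(tis, stop_on_error = TRUE) {
  fail <- function(msg) {
    if (stop_on_error) stop(msg) else return(FALSE)
  }
  if (any(lengths(tis$cells) < 3L))
    return(fail("cell with fewer than 3 vertices"))
  vcount <- tabulate(unlist(tis$cells, use.names = FALSE),
                     nbins = nrow(tis$vertices))
  if (any(vcount != 3L))
    return(fail(sprintf("vertex not shared by exactly 3 cells (e.g. vertex %d in %d cells)",
                        which(vcount != 3L)[1], vcount[which(vcount != 3L)[1]])))
  # directed edges: every unordered pair must occur once in each direction
  from <- unlist(lapply(tis$cells, function(cc) cc), use.names = FALSE)
  to <- unlist(lapply(tis$cells, function(cc) c(cc[-1], cc[1])),
               use.names = FALSE)
  key <- paste(pmin(from, to), pmax(from, to))
  dir <- from < to
  tab <- split(dir, key)
  ok <- vapply(tab, function(d) length(d) == 2L && sum(d) == 1L, logical(1))
  if (!all(ok))
    return(fail(sprintf("edge %s not shared by two cells with opposite traversal",
                        names(tab)[!ok][1])))
  g <- tryCatch(cell_geometry(tis), error = function(e) e)
  if (inherits(g, "error")) return(fail(conditionMessage(g)))
  invisible(TRUE)
}

# ---- periodic Voronoi initial condition -----------------------------------

# area centroid of a simple polygon (used by Lloyd iteration)
poly_area_centroid <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  cr <- p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]
  a <- sum(cr) / 2
  c(sum((p[, 1] + p[i2, 1]) * cr), sum((p[, 2] + p[i2, 2]) * cr)) / (6 * a)
}

# Voronoi tessellation of points in a periodic box, via Delaunay of the
# points augmented with ghost copies in a margin around the box. Junctions
# are identified combinatorially by the (unordered) triple of canonical seed
# ids of their Delaunay triangle, which is exact: two convex Voronoi cells
# share at most one edge, so a triple determines a unique junction.
periodic_voronoi <- function(pts, box, margin_factor = 3.5) {
  n <- nrow(pts)
  pts <- wrap_box(pts, box)
  spacing <- sqrt(box[1] * box[2] / n)
  m <- margin_factor * spacing
  shifts <- expand.grid(sx = -1:1, sy = -1:1)
  shifts <- shifts[!(shifts$sx == 0 & shifts$sy == 0), ]
  ghosts <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
    q <- cbind(pts[, 1] + shifts$sx[k] * box[1],
               pts[, 2] + shifts$sy[k] * box[2])
    keep <- q[, 1] > -m & q[, 1] < box[1] + m &
      q[, 2] > -m & q[, 2] < box[2] + m
    cbind(q[keep, , drop = FALSE], which(keep))
  }))
  allp <- rbind(pts, ghosts[, 1:2, drop = FALSE])
  orig <- c(seq_len(n), as.integer(ghosts[, 3]))
  tri <- .delaunay_cpp(allp)

  # circumcenters, vectorised
  ax <- allp[tri[, 1], 1]; ay <- allp[tri[, 1], 2]
  bx <- allp[tri[, 2], 1]; by <- allp[tri[, 2], 2]
  cx <- allp[tri[, 3], 1]; cy <- allp[tri[, 3], 2]
  d <- 2 * ((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ccx <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  ccy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d

  # triangles incident to each central point
  inc_pt <- c(tri[, 1], tri[, 2], tri[, 3])
  inc_tri <- rep.int(seq_len(nrow(tri)), 3L)
  keep <- inc_pt <= n
  inc <- split(inc_tri[keep], inc_pt[keep])

  key <- vapply(seq_len(nrow(tri)), function(t) {
    paste(sort(orig[tri[t, ]]), collapse = "_")
  }, character(1))

  vmap <- new.env(hash = TRUE, parent = emptyenv())
  vpos <- matrix(NA_real_, nrow(tri), 2)
  nvert <- 0L
  cells <- vector("list", n)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- inc[[as.character(i)]]
    if (is.null(tt) || length(tt) < 3L)
      stop("degenerate Voronoi cell for seed ", i)
    ang <- atan2(ccy[tt] - pts[i, 2], ccx[tt] - pts[i, 1])
    tt <- tt[order(ang)]
    polys[[i]] <- cbind(ccx[tt], ccy[tt])
    ids <- integer(length(tt))
    for (j in seq_along(tt)) {
      k <- key[tt[j]]
      id <- vmap[[k]]
      if (is.null(id)) {
        nvert <- nvert + 1L
        id <- nvert
        vmap[[k]] <- id
        vpos[id, ] <- wrap_box(c(ccx[tt[j]], ccy[tt[j]]), box)
      }
      ids[j] <- id
    }
    cells[[i]] <- ids
  }
  list(vertices = vpos[seq_len(nvert), , drop = FALSE], cells = cells,
       polys = polys, seeds = pts)
}

#' Generate a random periodic tissue
#'
#' Builds a disordered near-isotropic polygonal tiling: uniform random seed
#' points in a periodic square box of area `n_cells` (preferred cell area 1),
#' Voronoi tessellation, and a fixed number of Lloyd relaxation steps to
#' regularise cell sizes. The construction is a deterministic function of
#' `(n_cells, seed)`.
#'
#' @param n_cells number of cells (>= 16, so that a central cluster plus
#'   surrounding rings can fit).
#' @param seed integer seed; same `(n_cells, seed)` reproduces the identical
#'   mesh bit for bit.
#' @param lloyd_steps number of Lloyd (centroidal Voronoi) iterations.
#'   Enough steps matter mechanically: they narrow the cell-area spread, and
#'   for the reference parameters the energy is non-convex in area below
#'   about 0.15, so under-regularised runt cells would collapse during
#'   relaxation.
#' @param mean_area mean cell area setting the box size (box area =
#'   `n_cells * mean_area`). The default is the area at which a single
#'   regular hexagon has zero isotropic stress under `params`, so the
#'   generated tissue starts close to its zero-net-stress box.
#' @param params [mechanical_params()] used only to derive the default
#'   `mean_area`.
#' @return A valid [tissue()] with `2 * n_cells` vertices (Euler relation for
#'   a tricellular periodic tiling).
#' @export
generate_tissue <- function(n_cells, seed, lloyd_steps = 30,
                            mean_area = NULL,
                            params = mechanical_params()) {
  if (!is.numeric(n_cells) || n_cells < 16)
    stop("`n_cells` must be >= 16 (cluster plus surrounding rings cannot fit)")
  n_cells <- as.integer(n_cells)
  mean_area <- mean_area %||% hexagon_zero_stress_area(params)
  L <- sqrt(n_cells * mean_area)
  box <- c(L, L)
  pts <- with_seed(seed, matrix(runif(2 * n_cells, 0, L), ncol = 2))
  vor <- NULL
  for (it in seq_len(lloyd_steps + 1L)) {
    vor <- periodic_voronoi(pts, box)
    if (it <= lloyd_steps)
      pts <- wrap_box(t(vapply(vor$polys, poly_area_centroid, numeric(2))),
                      box)
  }
  tis <- tissue(vor$vertices, vor$cells, box)
  validate_tissue(tis)
  tis
}

#' Zero-stress area of a regular hexagonal cell
#'
#' Area `A` at which a regular hexagon (perimeter `L = c sqrt(A)`,
#' `c = 6 / sqrt(3 sqrt(3) / 2)`) has zero isotropic stress [peff()] under
#' the given parameters. Used to size the initial simulation box so the
#' tissue starts near its zero-net-stress state.
#'
#' @param params a [mechanical_params()].
#' @return single numeric area (dimensionless).
#' @export
hexagon_zero_stress_area <- function(params = mechanical_params()) {
  cc <- 6 / sqrt(3 * sqrt(3) / 2)
  f <- function(A) A - 1 + params$gamma * cc^2 / 2 -
    params$lambda * cc / (4 * sqrt(A))
  if (f(1e-4) > 0 || f(4) < 0) return(1)
  stats::uniroot(f, c(1e-4, 4), tol = 1e-10)$root
}

# ---- adjacency -------------------------------------------------------------

# cell adjacency list: cells sharing an edge (an unordered vertex pair)
cell_adjacency <- function(tis) {
  nc <- length(tis$cells)
  from <- unlist(tis$cells, use.names = FALSE)
  to <- unlist(lapply(tis$cells, function(cc) c(cc[-1], cc[1])),
               use.names = FALSE)
  cellid <- rep.int(seq_len(nc), lengths(tis$cells))
  key <- paste(pmin(from, to), pmax(from, to))
  pair <- split(cellid, key)
  adj <- vector("list", nc)
  for (p in pair) {
    if (length(p) == 2L) {
      adj[[p[1]]] <- c(adj[[p[1]]], p[2])
      adj[[p[2]]] <- c(adj[[p[2]]], p[1])
    }
  }
  lapply(adj, unique)
}

# edges between a cluster cell and a non-cluster cell, as a list of
# 2x2 coordinate matrices (endpoints resolved in the cluster cell's frame)
cluster_boundary_segments <- function(tis) {
  if (!any(tis$cluster)) stop("tissue has no cluster cells flagged")
  segs <- list()
  nc <- length(tis$cells)
  from <- unlist(tis$cells, use.names = FALSE)
  to <- unlist(lapply(tis$cells, function(cc) c(cc[-1], cc[1])),
               use.names = FALSE)
  cellid <- rep.int(seq_len(nc), lengths(tis$cells))
  key <- paste(pmin(from, to), pmax(from, to))
  cl <- split(tis$cluster[cellid], key)
  vv <- split(data.frame(from, to), key)
  is_bnd <- vapply(cl, function(z) length(z) == 2L && xor(z[1], z[2]),
                   logical(1))
  for (k in which(is_bnd)) {
    e <- vv[[k]][1, ]
    a <- tis$vertices[e$from, ]
    b <- a + minimage(tis$vertices[e$to, ] - a, tis$box)
    segs[[length(segs) + 1L]] <- rbind(a, b)
  }
  segs
}

# mean (minimum-image) edge length of the mesh
mean_edge_length <- function(tis) {
  from <- unlist(tis$cells, use.names = FALSE)
  to <- unlist(lapply(tis$cells, function(cc) c(cc[-1], cc[1])),
               use.names = FALSE)
  d <- minimage(tis$vertices[to, , drop = FALSE] -
                  tis$vertices[from, , drop = FALSE], tis$box)
  mean(sqrt(rowSums(d^2)))
}

# ---- JSON mesh I/O ---------------------------------------------------------

#' Write / read a tissue mesh as JSON
#'
#' Round-trips the full mesh (box, vertices, cell cycles, gamma multipliers,
#' cluster flags) with full double precision.
#'
#' @param tis a [tissue()].
#' @param path file path.
#' @return `read_tissue_json` returns a [tissue()]; `write_tissue_json`
#'   returns `path` invisibly.
#' @export
write_tissue_json <- function(tis, path) {
  # %.17g preserves every double bit-exactly through a parse cycle
  num <- function(x) sprintf("%.17g", x)
  pair_rows <- function(m) paste0("[", num(m[, 1]), ",", num(m[, 2]), "]")
  txt <- paste0(
    "{\"box\":[", paste(num(tis$box), collapse = ","), "],",
    "\"vertices\":[", paste(pair_rows(tis$vertices), collapse = ","), "],",
    "\"cells\":[",
    paste(vapply(tis$cells, function(cc)
      paste0("[", paste(cc, collapse = ","), "]"), character(1)),
      collapse = ","), "],",
    "\"gamma_multiplier\":[", paste(num(tis$gamma_multiplier),
                                    collapse = ","), "],",
    "\"cluster\":[", paste(ifelse(tis$cluster, "true", "false"),
                           collapse = ","), "]}")
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_tissue_json
#' @export
read_tissue_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  verts <- if (is.list(obj$vertices)) do.call(rbind, obj$vertices)
  else obj$vertices
  cells <- if (is.list(obj$cells)) lapply(obj$cells, as.integer)
  else apply(obj$cells, 1, as.integer, simplify = FALSE)
  tissue(verts, cells, obj$box, obj$gamma_multiplier, obj$cluster)
}
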