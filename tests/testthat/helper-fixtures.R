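# Shared fixtures, built in code. Meshes are cached per (n_cells, seed) so
# expensive relaxed tissues are constructed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# a single free cell in a huge box (periodicity irrelevant); bypasses the
# tricellular-tiling invariants on purpose for geometry unit tests
single_cell_tissue <- function(poly, box = c(1000, 1000)) {
  tissue(poly, list(seq_len(nrow(poly))), box)
}

unit_square <- function() {
  cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
}

# regular hexagon, circumradius r, centred at (cx, cy)
hexagon <- function(r = 1, cx = 0, cy = 0) {
  th <- pi / 3 * (0:5)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- expr
  .fixture_cache[[key]]
}

relaxed_tissue <- function(n_cells, seed, params = mechanical_params()) {
  cached(sprintf("relaxed_%d_%d", n_cells, seed), {
    suppressWarnings(relax(generate_tissue(n_cells, seed = seed), params))
  })
}

zeroed_tissue <- function(n_cells, seed, params = mechanical_params()) {
  cached(sprintf("zeroed_%d_%d", n_cells, seed), {
    suppressWarnings(zero_net_stress(relaxed_tissue(n_cells, seed, params),
                                     params))
  })
}

clustered_tissue <- function(n_cells, seed, increment, target_size = 19) {
  cached(sprintf("clustered_%d_%d_%g", n_cells, seed, increment), {
    par_i <- mechanical_params(cluster_increment = increment)
    suppressWarnings(apply_cluster(zeroed_tissue(n_cells, seed), par_i,
                                   target_size = target_size))
  })
}

# brute-force 1D optimal transport oracle between two empirical measures:
# equal sizes by exhaustive assignment enumeration, unequal sizes by
# common-refinement replication (both independent of the ECDF integral)
wasserstein_oracle <- function(a, b) {
  n <- length(a)
  m <- length(b)
  if (n == m) {
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
      out
    }
    best <- Inf
    for (p in perms(seq_len(n)))
      best <- min(best, mean(abs(a - b[p])))
    best
  } else {
    gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)
    l <- (n * m) / gcd(n, m)
    mean(abs(sort(rep(sort(a), each = l / n)) -
               sort(rep(sort(b), each = l / m))))
  }
}
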