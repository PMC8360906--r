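# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so no global state leaks out of the
# package (all randomness flows from explicit seeds).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream seed from a master seed; kept below 2^31.
derive_seed <- function(master, stream) {
  as.integer((as.double(master) * 48271 + 104729 * as.double(stream)) %%
               2147483647)
}

# minimum-image displacement in a periodic box (vectorised over rows)
minimage <- function(d, box) {
  if (is.null(box)) return(d)
  if (is.matrix(d)) {
    d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
    d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
    d
  } else {
    d - box * round(d / box)
  }
}

# wrap coordinates into [0, Lx) x [0, Ly)
wrap_box <- function(p, box) {
  if (is.null(box)) return(p)
  if (is.matrix(p)) {
    p[, 1] <- p[, 1] - box[1] * floor(p[, 1] / box[1])
    p[, 2] <- p[, 2] - box[2] * floor(p[, 2] / box[2])
    p
  } else {
    p - box * floor(p / box)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
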