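p_ref <- mechanical_params()

test_that("a relaxed tissue is a fixed point of relaxation", {
  tis <- relaxed_tissue(64, 3)
  e0 <- total_energy(tis, p_ref)
  again <- suppressWarnings(relax(tis, p_ref))
  expect_equal(total_energy(again, p_ref), e0, tolerance = 1e-10)
  expect_lt(max(abs(again$vertices - tis$vertices)), 1e-4)
})

test_that("relaxation recovers the minimum after a small perturbation", {
  tis <- relaxed_tissue(64, 3)
  e0 <- total_energy(tis, p_ref)
  pert <- tis
  noise <- epimech:::with_seed(21,
    matrix(rnorm(length(tis$vertices), sd = 0.01), ncol = 2))
  pert$vertices <- pert$vertices + noise
  expect_gt(total_energy(pert, p_ref), e0)
  back <- suppressWarnings(relax(pert, p_ref, t1 = FALSE))
  expect_lt(total_energy(back, p_ref) - e0, 1e-6)
  expect_true(attr(back, "converged"))
  # descent contract: recorded stage energies never increase
  tr <- attr(back, "energy_trace")
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("T1 swap exchanges neighbours and preserves the tiling invariants", {
  tis <- relaxed_tissue(64, 3)
  # pick an interior edge and collapse it below threshold by hand
  from <- unlist(tis$cells)
  to <- unlist(lapply(tis$cells, function(cc) c(cc[-1], cc[1])))
  keep <- from < to
  e <- cbind(from[keep], to[keep])
  adj_before <- epimech:::cell_adjacency(tis)
  pick <- NA
  for (i in seq_len(nrow(e))) {
    cells_ab <- which(vapply(tis$cells, function(cc)
      all(e[i, ] %in% cc), logical(1)))
    if (length(cells_ab) == 2L &&
        all(lengths(tis$cells[cells_ab]) >= 5L)) { pick <- i; break }
  }
  v1 <- e[pick, 1]; v2 <- e[pick, 2]
  mid <- tis$vertices[v1, ] +
    epimech:::minimage(tis$vertices[v2, ] - tis$vertices[v1, ], tis$box) / 2
  d <- epimech:::minimage(tis$vertices[v2, ] - tis$vertices[v1, ], tis$box)
  tis$vertices[v1, ] <- mid - d * 1e-4
  tis$vertices[v2, ] <- mid + d * 1e-4
  swapped <- epimech:::t1_swap(tis, v1, v2, new_length = 0.05)
  expect_false(is.null(swapped))
  expect_true(validate_tissue(swapped))
  AB <- which(vapply(tis$cells, function(cc) all(c(v1, v2) %in% cc),
                     logical(1)))
  adj_after <- epimech:::cell_adjacency(swapped)
  # the two cells that shared the collapsed edge are no longer neighbours
  expect_false(AB[2] %in% adj_after[[AB[1]]])
  expect_true(AB[2] %in% adj_before[[AB[1]]])
})

test_that("zero_net_stress reaches zero mean stress and responds to box strain", {
  tz <- zeroed_tissue(100, 1)
  expect_lte(abs(mean_peff(tz, p_ref)), 1e-4)
  shrink <- tz
  shrink$vertices <- shrink$vertices * 0.96
  shrink$box <- shrink$box * 0.96
  shrink <- suppressWarnings(relax(shrink, p_ref))
  expect_lt(mean_peff(shrink, p_ref), 0) # compression
  grow <- tz
  grow$vertices <- grow$vertices * 1.04
  grow$box <- grow$box * 1.04
  grow <- suppressWarnings(relax(grow, p_ref))
  expect_gt(mean_peff(grow, p_ref), 0) # tension
})

test_that("apply_cluster flags a connected central cluster of the right size", {
  tc <- clustered_tissue(100, 1, 0.1, target_size = 19)
  expect_gte(sum(tc$cluster), 19)
  expect_equal(unique(tc$gamma_multiplier[tc$cluster]), 1.1)
  expect_equal(unique(tc$gamma_multiplier[!tc$cluster]), 1)
  # edge-connectivity of the flagged set
  adj <- epimech:::cell_adjacency(tc)
  cl <- which(tc$cluster)
  seen <- cl[1]
  repeat {
    nxt <- unique(c(seen, intersect(unlist(adj[seen]), cl)))
    if (length(nxt) == length(seen)) break
    seen <- nxt
  }
  expect_setequal(seen, cl)
  expect_error(apply_cluster(zeroed_tissue(100, 1), p_ref, target_size = 30),
               "quarter")
})

test_that("a zero cluster increment perturbs nothing", {
  tz <- zeroed_tissue(100, 1)
  tc <- suppressWarnings(apply_cluster(tz, mechanical_params(), 19))
  expect_lt(max(abs(epimech:::minimage(tc$vertices - tz$vertices, tz$box))),
            1e-6)
  expect_lte(abs(mean_peff(tc, mechanical_params())), 1e-3)
})
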