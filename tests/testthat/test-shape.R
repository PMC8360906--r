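test_that("centroid is the vertex mean and translates equivariantly", {
  sq <- cbind(c(-0.5, 0.5, 0.5, -0.5), c(-0.5, -0.5, 0.5, 0.5))
  expect_equal(poly_centroid(sq), c(0, 0))
  tri <- rbind(c(0, 0), c(3, 0), c(0, 3))
  expect_equal(poly_centroid(tri), c(1, 1))
  shifted <- sweep(tri, 2, c(2.5, -1.5), FUN = "+")
  expect_equal(poly_centroid(shifted), c(1, 1) + c(2.5, -1.5))
  # cyclic relabeling leaves it unchanged
  expect_equal(poly_centroid(tri[c(2, 3, 1), ]), poly_centroid(tri))
})

test_that("shape tensor matches hand-computed second moments", {
  sq <- cbind(c(-0.5, 0.5, 0.5, -0.5), c(-0.5, -0.5, 0.5, 0.5))
  expect_equal(shape_tensor(sq), matrix(c(0.25, 0, 0, 0.25), 2),
               tolerance = 1e-12)
  rect <- cbind(c(-1, 1, 1, -1), c(-0.5, -0.5, 0.5, 0.5))
  expect_equal(shape_tensor(rect), matrix(c(1, 0, 0, 0.25), 2),
               tolerance = 1e-12)
  # regular hexagon: mean of cos^2 over six evenly spaced angles is 1/2
  expect_equal(shape_tensor(hexagon(1)), diag(2) * 0.5, tolerance = 1e-12)
})

test_that("shape tensor is rotation equivariant; circularity is scale invariant", {
  set.seed(31)
  for (rep in 1:5) {
    poly <- cbind(runif(6, -1, 1) + c(3, 2, 1, -1, -2, -3),
                  runif(6, -1, 1))
    th <- runif(1, 0, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    S <- shape_tensor(poly)
    Srot <- shape_tensor(t(R %*% t(poly)))
    expect_equal(Srot, R %*% S %*% t(R), tolerance = 1e-10)
    expect_equal(circularity(S * 9), circularity(S), tolerance = 1e-12)
    expect_equal(shape_tensor(poly * 3), S * 9, tolerance = 1e-10)
  }
})

test_that("principal axis and circularity behave on canonical shapes", {
  rect <- cbind(c(-1, 1, 1, -1), c(-0.5, -0.5, 0.5, 0.5))
  ax <- principal_axis(shape_tensor(rect))
  expect_true(ax$defined)
  expect_equal(ax$angle_deg, 0)
  expect_equal(circularity(shape_tensor(rect)), 0.25, tolerance = 1e-12)
  sq <- cbind(c(-0.5, 0.5, 0.5, -0.5), c(-0.5, -0.5, 0.5, 0.5))
  expect_false(principal_axis(shape_tensor(sq))$defined)
  expect_equal(circularity(shape_tensor(sq)), 1)
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ax30 <- principal_axis(shape_tensor(t(R %*% t(rect))))
  expect_equal(ax30$angle_deg, 30, tolerance = 1e-6)
  expect_error(circularity(matrix(0, 2, 2)), "degenerate")
})

test_that("ring distances equal an exhaustive shortest-path oracle", {
  tis <- generate_tissue(36, seed = 8)
  adj <- epimech:::cell_adjacency(tis)
  cl <- rep(FALSE, 36)
  cl[c(5, 9)] <- TRUE
  ring <- ring_distance(adj, cl)
  expect_identical(ring[c(5, 9)], c(0L, 0L))
  expect_true(all(ring[unlist(adj[c(5, 9)])] <= 1L))
  g <- igraph::graph_from_adj_list(adj, mode = "all")
  d_or <- apply(igraph::distances(g, v = which(cl)), 2, min)
  expect_identical(as.integer(ring), as.integer(d_or))
  expect_error(ring_distance(adj, rep(FALSE, 36)), "no cluster")
})

test_that("ring categories follow the three-band grouping", {
  expect_identical(ring_category(c(0, 1, 3, 4, 6, 7, 12)),
                   c("cluster", "1-3", "1-3", "4-6", "4-6", "7+", "7+"))
})

test_that("orientation to cluster folds angles into [0, 90]", {
  seg <- list(rbind(c(10, -5), c(10, 5))) # vertical boundary to the right
  cen <- rbind(c(0, 0))
  # reference vector is +x; nearest-boundary and centroid conventions agree
  for (refmode in c("boundary", "centroid")) {
    expect_equal(orientation_to_cluster(cen, 0, seg, reference = refmode), 0)
    expect_equal(orientation_to_cluster(cen, 90, seg, reference = refmode),
                 90)
    expect_equal(orientation_to_cluster(cen, 30, seg, reference = refmode),
                 30)
    expect_equal(orientation_to_cluster(cen, 150, seg, reference = refmode),
                 30) # acute folding
  }
  expect_true(is.na(orientation_to_cluster(cen, NA_real_, seg)))
})

test_that("division orientation is axis-symmetric", {
  seg <- list(rbind(c(10, -5), c(10, 5)))
  expect_equal(division_orientation(c(1, 0), c(0, 0), seg), 0)
  expect_equal(division_orientation(c(0, 1), c(0, 0), seg), 90)
  a60 <- c(cos(pi / 3), sin(pi / 3))
  expect_equal(division_orientation(a60, c(0, 0), seg), 60,
               tolerance = 1e-10)
  expect_equal(division_orientation(-a60, c(0, 0), seg), 60,
               tolerance = 1e-10)
  expect_error(division_orientation(c(0, 0), c(0, 0), seg), "zero-length")
})

test_that("division rate is percent of cells dividing per minute", {
  expect_equal(division_rate(6, 100, 30), 0.2)
  expect_equal(division_rate(0, 100, 30), 0)
  expect_equal(division_rate(6, 100, 60), 0.1)
  expect_error(division_rate(1, 0, 30), "positive")
  expect_error(division_rate(1, 100, 0), "positive")
})

test_that("rose histogram bins by 10 degrees with a closed last bin", {
  counts <- rose_histogram(c(5, 15, 85, 90))
  expect_identical(unname(counts), c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 2L))
  expect_identical(unname(rose_histogram(numeric(0))), rep(0L, 9))
  expect_error(rose_histogram(c(5, 95)), "95")
  set.seed(13)
  big <- rose_histogram(runif(9000, 0, 90))
  expect_identical(sum(big), 9000L)
  # multinomial: each bin 1000 +/- 5 sd
  expect_true(all(abs(big - 1000) < 5 * sqrt(9000 * (1 / 9) * (8 / 9))))
})

test_that("tissue measurement excludes undefined axes and fills every column", {
  tc <- clustered_tissue(100, 1, 0.1, target_size = 19)
  m <- measure_tissue(tc, mechanical_params(cluster_increment = 0.1))
  expect_identical(nrow(m), 100L)
  expect_true(all(m$ring[m$is_cluster] == 0))
  expect_true(all(m$ring[!m$is_cluster] >= 1))
  expect_true(all(m$circularity > 0 & m$circularity <= 1))
  ok <- !is.na(m$orientation_to_cluster)
  expect_true(all(m$orientation_to_cluster[ok] >= 0 &
                    m$orientation_to_cluster[ok] <= 90))
  expect_true(all(is.na(m$orientation_to_cluster[m$is_cluster])))
  expect_gte(attr(m, "n_axis_undefined"), 0)
})

test_that("orientations near an unperturbed cluster are uniform on [0, 90]", {
  # null model: flag a central patch without any contractility change and
  # pool ring 1-3 orientations over 10 tissues; the distribution must be
  # indistinguishable from uniform
  p0 <- mechanical_params(cluster_increment = 0)
  ang <- unlist(lapply(1:10, function(s) {
    m <- measure_tissue(clustered_tissue(400, s, 0), p0)
    m$orientation_to_cluster[m$ring_category == "1-3"]
  }))
  ang <- ang[!is.na(ang)]
  expect_gt(length(ang), 500)
  expect_gt(suppressWarnings(
    stats::ks.test(ang, "punif", 0, 90)$p.value), 0.01)
  expect_gt(median(ang), 40)
  expect_lt(median(ang), 50)
})
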