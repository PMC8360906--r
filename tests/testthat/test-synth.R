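test_that("synthetic tracings are deterministic in the master seed", {
  cfg <- synthetic_config(n_cells = 64, cluster_size = 7,
                          n_pseudo_embryos = 2, master_seed = 5)
  a <- synth_tracings(cfg)
  b <- synth_tracings(cfg)
  expect_identical(a, b)
  cfg2 <- synthetic_config(n_cells = 64, cluster_size = 7,
                           n_pseudo_embryos = 2, master_seed = 6)
  expect_false(identical(synth_tracings(cfg2), a))
  # exported CSV is byte-identical across runs
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(a, f1, row.names = FALSE)
  write.csv(b, f2, row.names = FALSE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("tracing tables carry well-formed polygons and a cluster", {
  cfg <- synthetic_config(n_cells = 64, cluster_size = 7,
                          n_pseudo_embryos = 1, master_seed = 5)
  trac <- synth_tracings(cfg)
  expect_named(trac, c("embryo_id", "cell_id", "vertex_order", "x", "y",
                       "is_cluster"))
  expect_true(any(trac$is_cluster))
  m <- measure_tracings(trac, box = attr(trac, "box"))
  expect_identical(nrow(m), 64L)
  expect_identical(sum(m$ring == 0), sum(m$is_cluster))
  expect_true(all(m$ring[!m$is_cluster] >= 1))
})

test_that("tracing measurement agrees with direct tissue measurement when noise-free", {
  cfg <- synthetic_config(n_cells = 100, cluster_size = 19,
                          n_pseudo_embryos = 1, vertex_jitter_sigma = 0,
                          true_increment = 0.2, master_seed = 3)
  trac <- synth_tracings(cfg)
  mt <- measure_tracings(trac, box = attr(trac, "box"))
  # rebuild the same tissue directly
  par1 <- mechanical_params(cluster_increment = 0.2)
  seed_e <- epimech:::derive_seed(3, 1)
  tis <- suppressWarnings(relax(generate_tissue(100, seed = seed_e), par1))
  tis <- suppressWarnings(zero_net_stress(tis, mechanical_params()))
  tis <- suppressWarnings(apply_cluster(tis, par1, 19))
  md <- measure_tissue(tis, par1)
  expect_identical(mt$ring[order(mt$cell_id)], md$ring)
  expect_equal(sort(mt$orientation_to_cluster),
               sort(md$orientation_to_cluster), tolerance = 1e-6)
})

test_that("synthetic recoil traces follow the saturation model", {
  cfg <- synthetic_config(recoil = list(sigma_frac = 0, n_traces = 1),
                          master_seed = 2)
  tr <- synth_recoil(cfg)
  one <- tr[tr$trace_id == 1, ]
  g <- cfg$recoil$groups[1, ]
  expect_equal(one$distance[one$time_s <= 0],
               rep(g$d0, sum(one$time_s <= 0)))
  f <- fit_kelvin_voigt(one[, c("time_s", "distance")])
  expect_equal(f$D, g$D, tolerance = 1e-6)
  expect_equal(f$k, g$k, tolerance = 1e-6)
  # frame interval: 4 s
  expect_equal(unique(diff(one$time_s)), 4)
  expect_identical(synth_recoil(cfg), tr)
})

test_that("noise level controls the residual of the true curve", {
  rms_at <- function(sf) {
    cfg <- synthetic_config(recoil = list(sigma_frac = sf, n_traces = 20),
                            master_seed = 11)
    tr <- synth_recoil(cfg)
    g <- cfg$recoil$groups
    res <- unlist(lapply(seq_len(nrow(g)), function(i) {
      d <- tr[tr$group == g$group[i], ]
      mu <- g$d0[i] + g$D[i] * (1 - exp(-g$k[i] * pmax(d$time_s, 0)))
      d$distance - mu
    }))
    sqrt(mean(res^2))
  }
  r1 <- rms_at(0.05)
  r2 <- rms_at(0.10)
  expect_equal(r2 / r1, 2, tolerance = 0.1)
})

test_that("division events match their configured rate and angular model", {
  cfg <- synthetic_config(divisions = list(rate = 0.2, n_cells = 400,
                                           duration_min = 300, kappa = 0),
                          master_seed = 21)
  ev <- synth_divisions(cfg)
  lambda <- 0.2 / 100 * 400 * 300
  expect_lt(abs(nrow(ev) - lambda), 5 * sqrt(lambda))
  dm <- division_metrics(ev)
  # measured in-plane CDR is the configured rate thinned by in_plane_prob
  expect_equal(dm$cdr, 0.2 * cfg$divisions$in_plane_prob, tolerance = 0.15)
  # kappa = 0: flat rose histogram
  expect_gt(suppressWarnings(
    stats::chisq.test(dm$rose)$p.value), 0.001)
  # strong concentration: most angles near 0
  cfg10 <- synthetic_config(divisions = list(rate = 0.2, n_cells = 400,
                                             duration_min = 300,
                                             kappa = 10),
                            master_seed = 21)
  dm10 <- division_metrics(synth_divisions(cfg10))
  expect_gt(mean(dm10$cdo_deg <= 30), 0.5)
  expect_lt(median(dm10$cdo_deg), median(dm$cdo_deg))
  expect_identical(synth_divisions(cfg10), synth_divisions(cfg10))
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(synth_recoil(synthetic_config(master_seed = 4)))
  invisible(synth_divisions(synthetic_config(master_seed = 4)))
  expect_identical(.Random.seed, before)
})
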