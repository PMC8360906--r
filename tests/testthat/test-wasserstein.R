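test_that("Wasserstein distance reproduces hand-computed cases", {
  expect_equal(wasserstein_1d(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(wasserstein_1d(0, 90), 90)
  # equal sizes: mean of sorted pairwise gaps (20 + 20) / 2
  expect_equal(wasserstein_1d(c(0, 30), c(20, 50)), 20)
  expect_error(wasserstein_1d(numeric(0), 1), "empty")
})

test_that("Wasserstein engine agrees with brute-force transport on all small sizes", {
  set.seed(17)
  for (n in 1:6) {
    for (m in 1:6) {
      for (rep in 1:4) {
        a <- round(runif(n, 0, 90), 1)
        b <- round(runif(m, 0, 90), 1)
        expect_equal(wasserstein_1d(a, b), wasserstein_oracle(a, b),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("Wasserstein distance satisfies the metric axioms", {
  set.seed(23)
  for (rep in 1:40) {
    a <- runif(sample(1:8, 1), 0, 90)
    b <- runif(sample(1:8, 1), 0, 90)
    cc <- runif(sample(1:8, 1), 0, 90)
    dab <- wasserstein_1d(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, wasserstein_1d(b, a), tolerance = 1e-12)
    expect_lte(dab, wasserstein_1d(a, cc) + wasserstein_1d(cc, b) + 1e-12)
  }
  # identity of indiscernibles for empirical measures
  a <- c(3, 1, 2)
  expect_equal(wasserstein_1d(a, c(2, 3, 1)), 0)
  expect_gt(wasserstein_1d(a, c(2, 3, 1.5)), 0)
})

test_that("distance equals the area between the empirical CDFs", {
  set.seed(29)
  a <- runif(7, 0, 90)
  b <- runif(11, 0, 90)
  grid <- seq(-1, 91, by = 0.001)
  riemann <- sum(abs(orientation_ecdf(a)(grid) - orientation_ecdf(b)(grid))) *
    0.001
  expect_equal(wasserstein_1d(a, b), riemann, tolerance = 1e-2)
})

test_that("orientation ECDF is a proper right-continuous step function", {
  f <- orientation_ecdf(45)
  expect_equal(f(44.999), 0)
  expect_equal(f(45), 1)
  g <- orientation_ecdf(c(10, 20))
  expect_equal(g(c(5, 10, 15, 20, 1e6)), c(0, 0.5, 0.5, 1, 1))
  expect_error(orientation_ecdf(numeric(0)), "empty")
})

test_that("summed distance adds the three category distances", {
  mk <- function(a13, a46, a7) orientation_dataset(
    list("1-3" = a13, "4-6" = a46, "7+" = a7), "simulation")
  sim <- mk(c(10, 20), c(30, 40), c(50, 60))
  same <- mk(c(10, 20), c(30, 40), c(50, 60))
  expect_equal(summed_distance(sim, same)$total, 0)
  only13 <- mk(c(15, 25), c(30, 40), c(50, 60))
  r <- summed_distance(sim, only13)
  expect_equal(r$total, unname(r$distances["1-3"]))
  expect_equal(unname(r$distances["1-3"]), wasserstein_1d(c(10, 20),
                                                          c(15, 25)))
  # symmetric, and equal to the sum of hand-computed per-category distances
  other <- mk(c(0, 90), c(45), c(10, 20, 80))
  r2 <- summed_distance(sim, other)
  expect_equal(r2$total, wasserstein_1d(c(10, 20), c(0, 90)) +
                 wasserstein_1d(c(30, 40), 45) +
                 wasserstein_1d(c(50, 60), c(10, 20, 80)),
               tolerance = 1e-12)
  expect_equal(summed_distance(other, sim)$total, r2$total)
})

test_that("empty categories are errors when one-sided, warnings when shared", {
  full <- orientation_dataset(list("1-3" = 1:5, "4-6" = 1:5, "7+" = 1:5),
                              "simulation")
  partial <- orientation_dataset(list("1-3" = 1:5, "4-6" = 1:5,
                                      "7+" = numeric(0)), "experiment")
  expect_error(summed_distance(full, partial), "7\\+")
  both <- orientation_dataset(list("1-3" = 1:5, "4-6" = 1:5,
                                   "7+" = numeric(0)), "simulation")
  expect_warning(r <- summed_distance(both, partial), "7\\+")
  expect_equal(unname(r$distances["7+"]), 0)
})

test_that("orientation datasets validate their categories and ranges", {
  expect_error(orientation_dataset(list("1-3" = 1:5), "experiment"),
               "missing")
  expect_error(orientation_dataset(list("1-3" = c(10, 95), "4-6" = 1,
                                        "7+" = 1), "experiment"),
               "outside")
})
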