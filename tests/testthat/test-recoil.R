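make_trace <- function(d0 = 10, D = 2, k = 0.1, dt = 4, n = 30, n_pre = 3,
                       sigma = 0, seed = 1) {
  t <- c(-(n_pre:1) * dt, (0:(n - 1)) * dt)
  mu <- d0 + D * (1 - exp(-k * pmax(t, 0)))
  eps <- if (sigma > 0) epimech:::with_seed(seed, rnorm(length(t),
                                                        sd = sigma))
  else 0
  data.frame(time_s = t, distance = mu + eps)
}

test_that("noiseless Kelvin-Voigt traces are recovered exactly", {
  f <- fit_kelvin_voigt(make_trace(d0 = 10, D = 2, k = 0.5))
  expect_equal(f$D, 2, tolerance = 1e-6)
  expect_equal(f$k, 0.5, tolerance = 1e-6)
  expect_equal(f$initial_recoil, 1, tolerance = 1e-6)
  f2 <- fit_kelvin_voigt(make_trace(d0 = 10, D = 2, k = 0.1))
  expect_equal(f2$k, 0.1, tolerance = 1e-6)
  expect_identical(f$initial_recoil, f$D * f$k)
  expect_lt(f$residual_rms, 1e-9)
  expect_true(f$converged)
  expect_false(f$negative_D)
})

test_that("a constant trace yields no recoil", {
  tr <- make_trace(D = 0)
  f <- fit_kelvin_voigt(tr)
  expect_lt(abs(f$D), 1e-6)
  expect_lt(abs(f$initial_recoil), 1e-6)
})

test_that("baseline-free mode recovers the same parameters on clean data", {
  f <- fit_kelvin_voigt(make_trace(d0 = 7, D = 1.5, k = 0.2),
                        fix_baseline = FALSE)
  expect_equal(f$d0, 7, tolerance = 1e-6)
  expect_equal(f$D, 1.5, tolerance = 1e-6)
  expect_equal(f$k, 0.2, tolerance = 1e-6)
})

test_that("fits are invariant to pre-ablation time origin and scale with units", {
  tr <- make_trace(d0 = 10, D = 2, k = 0.1, sigma = 0.05, seed = 5)
  f0 <- fit_kelvin_voigt(tr)
  # relabelled acquisition clock, re-anchored so ablation is again t = 0
  tr2 <- transform(tr, time_s = (time_s + 137) - 137)
  f2 <- fit_kelvin_voigt(tr2)
  expect_equal(f2$D, f0$D, tolerance = 1e-12)
  expect_equal(f2$k, f0$k, tolerance = 1e-12)
  # the pre-ablation history enters only through its baseline mean
  pre <- tr$time_s < 0
  tr3b <- rbind(data.frame(time_s = c(-40, -20),
                           distance = rep(mean(tr$distance[pre]), 2)),
                tr[!pre, ])
  f3b <- fit_kelvin_voigt(tr3b)
  expect_equal(f3b$D, f0$D, tolerance = 1e-8)
  expect_equal(f3b$k, f0$k, tolerance = 1e-8)
  # unit rescale: D and initial recoil scale, k does not
  tr3 <- transform(tr, distance = distance * 3.7)
  f3 <- fit_kelvin_voigt(tr3)
  expect_equal(f3$k, f0$k, tolerance = 1e-6)
  expect_equal(f3$D, 3.7 * f0$D, tolerance = 1e-6)
  expect_equal(f3$initial_recoil, 3.7 * f0$initial_recoil, tolerance = 1e-6)
})

test_that("k is recovered within 10 percent at 5 percent noise (median)", {
  errs <- vapply(1:100, function(r) {
    tr <- make_trace(d0 = 10, D = 2, k = 0.1, sigma = 0.05 * 2, seed = 1000 + r)
    f <- fit_kelvin_voigt(tr)
    abs(f$k - 0.1) / 0.1
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("recovery error grows with noise", {
  med_err <- vapply(c(0.02, 0.1, 0.4), function(s) {
    errs <- vapply(1:40, function(r) {
      f <- fit_kelvin_voigt(make_trace(sigma = s, seed = 400 + r))
      abs(f$k - 0.1) / 0.1
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) > 0))
})

test_that("traces are validated", {
  tr <- make_trace()
  expect_error(fit_kelvin_voigt(tr[tr$time_s >= 0, ]), "pre-ablation")
  expect_error(fit_kelvin_voigt(tr[tr$time_s <= 8, ]), "5 post-ablation")
  bad <- tr
  bad$time_s[5] <- bad$time_s[4]
  expect_error(fit_kelvin_voigt(bad), "increasing")
})

test_that("group summaries report means, SEMs and counts", {
  fits <- data.frame(trace_id = 1:6,
                     group = c("a", "a", "a", "b", "b", "c"),
                     initial_recoil = c(1, 2, 3, 5, 5, 7),
                     k = c(0.5, 0.4, 0.6, 0.5, 0.5, 0.3),
                     converged = TRUE)
  s <- initial_recoil_summary(fits)$summary
  a <- s[s$group == "a", ]
  expect_equal(a$mean_initial_recoil, 2)
  expect_equal(a$sem_initial_recoil, 1 / sqrt(3), tolerance = 1e-12)
  b <- s[s$group == "b", ]
  expect_equal(b$sem_initial_recoil, 0) # two identical fits
  cc <- s[s$group == "c", ]
  expect_true(is.na(cc$sem_initial_recoil)) # single fit: SEM absent
  expect_identical(s$n, c(3L, 2L, 1L))
})

test_that("a whole recoil table is fitted per trace", {
  cfg <- synthetic_config(recoil = list(n_traces = 3, sigma_frac = 0.02),
                          master_seed = 9)
  traces <- synth_recoil(cfg)
  fits <- fit_recoil_table(traces)
  expect_identical(nrow(fits), 9L) # 3 groups x 3 traces
  expect_true(all(fits$converged))
  expect_true(all(abs(fits$k - 0.1) / 0.1 < 0.25))
  grp <- initial_recoil_summary(fits)$summary
  # the synthetic cluster group has the largest recoil amplitude
  expect_gt(grp$mean_initial_recoil[grp$group == "cluster"],
            grp$mean_initial_recoil[grp$group == "wildtype"])
})
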