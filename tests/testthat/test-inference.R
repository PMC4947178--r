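test_that("with the variance frozen, per-cell updates match conjugate betas", {
  # single cell, x = 5 of n = 10, v = 1/12 at p_hat = 0.5 => Beta(6, 6)
  d <- site_dataset("chr1", 1, "+", cell_counts("c1", 5, 10),
                    bulk_counts(5, 10))
  post <- run_sampler(d, settings = sampler_settings(
    seed = 1, iterations = 20000, burn_in = 1000, fix_v = 1 / 12))
  expect_equal(mean(post$p[, 1]), 0.5, tolerance = 0.01)
  expect_equal(var(post$p[, 1]), 1 / 52, tolerance = 0.002)

  # random configurations against closed-form posterior moments
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    x <- sample(0:n, 1)
    m <- runif(1, 0.2, 0.8)
    v <- runif(1, 0.05, 0.8) * m * (1 - m)
    d <- site_dataset("chr1", 1, "+", cell_counts("c1", x, n),
                      bulk_counts(round(m * 1000), 1000))
    post <- run_sampler(d, settings = sampler_settings(
      seed = 100 + rep, iterations = 6000, burn_in = 500, fix_v = v))
    sh <- beta_shapes(post$p_hat, v)
    a <- sh[["alpha"]] + x
    b <- sh[["beta"]] + n - x
    mu <- a / (a + b)
    s2 <- a * b / ((a + b)^2 * (a + b + 1))
    expect_lt(abs(mean(post$p[, 1]) - mu), 4 * sqrt(s2 / 5500) + 1e-3)
    expect_lt(abs(var(post$p[, 1]) - s2), 0.15 * s2 + 1e-4)
  }
})

test_that("identical seed and settings give bitwise-identical draws", {
  sc <- simulate_scenario(preset_scenarios(seed = 3)[["high-var"]])
  a <- run_sampler(sc, settings = quick_settings(7))
  b <- run_sampler(sc, settings = quick_settings(7))
  expect_identical(a$v, b$v)
  expect_identical(a$p, b$p)
  c <- run_sampler(sc, settings = quick_settings(8))
  expect_false(identical(a$v, c$v))
})

test_that("cells without reads are retained and draw from the beta layer", {
  d <- site_dataset("chr1", 1, "+",
                    cell_counts(c("c1", "c2"), c(5, 0), c(10, 0)),
                    bulk_counts(50, 100))
  post <- run_sampler(d, settings = sampler_settings(
    seed = 4, iterations = 4000, burn_in = 500, fix_v = 0.02))
  expect_identical(ncol(post$p), 2L)
  # the uncovered cell's draws are prior-layer draws: mean ~ p_hat, var ~ v
  expect_lt(abs(mean(post$p[, 2]) - 0.5), 0.02)
  expect_lt(abs(var(post$p[, 2]) - 0.02), 0.005)
  expect_error(run_sampler(
    site_dataset("chr1", 1, "+", cell_counts("c1", 0, 0), bulk_counts(1, 10)),
    settings = quick_settings(1)), "no cell")
})

test_that("high-variance data push the variance posterior away from zero", {
  sc <- simulate_scenario(preset_scenarios(seed = 21)[["high-var"]])
  post <- run_sampler(sc, settings = quick_settings(22))
  expect_true(excludes_zero(hpd_interval(post$v)))
  expect_gt(mean(post$v), 0.05)
})

test_that("low-variance data accumulate the variance posterior towards zero", {
  sc <- simulate_scenario(preset_scenarios(seed = 23)[["low-var"]])
  post <- run_sampler(sc, settings = quick_settings(24))
  expect_lt(density_mode(post$v, upper = post$v_max), 0.02)
  expect_lt(mean(post$v), 0.02)
})

test_that("detection of high variance persists across the coverage sweep", {
  presets <- preset_scenarios(seed = 31)
  for (nm in c("cov100", "cov50", "cov20", "cov10")) {
    sc <- simulate_scenario(presets[[nm]])
    expect_identical(nrow(sc$cells), 20L)
    post <- run_sampler(sc, settings = quick_settings(32))
    expect_true(excludes_zero(hpd_interval(post$v)), label = nm)
  }
})

test_that("detection of high variance persists down to five cells", {
  presets <- preset_scenarios(seed = 33)
  for (nm in c("cells50", "cells20", "cells10", "cells5")) {
    sc <- simulate_scenario(presets[[nm]])
    expect_true(all(sc$cells$n == 20L))
    post <- run_sampler(sc, settings = quick_settings(34))
    expect_true(excludes_zero(hpd_interval(post$v)), label = nm)
  }
})

test_that("95% HPD intervals cover the generating variance in most replicates", {
  # data drawn from the model itself at p = 0.35, J = 20, coverage 20
  for (v_true in c(0.005, 0.05, 0.12)) {
    hits <- 0L
    for (rep in 1:25) {
      d <- model_draw_dataset(J = 20, coverage = 20, mean_rate = 0.35,
                              v_true = v_true, seed = 1000 * v_true + rep)
      post <- run_sampler(d, settings = quick_settings(500 + rep))
      hpd <- hpd_interval(post$v)
      if (hpd$lo <= v_true && v_true <= hpd$hi) hits <- hits + 1L
    }
    expect_gte(hits, 20L)  # >= 80% of 25
  }
})

test_that("the HPD interval is the shortest window with the requested mass", {
  set.seed(11)
  u <- runif(1e5)
  h <- hpd_interval(u, 0.95)
  expect_equal(h$hi - h$lo, 0.95, tolerance = 0.01)
  z <- rnorm(1e5)
  hz <- hpd_interval(z, 0.95)
  expect_lt(abs(hz$lo + 1.96), 0.05)
  expect_lt(abs(hz$hi - 1.96), 0.05)
  same <- hpd_interval(rep(3.2, 10))
  expect_identical(c(same$lo, same$hi), c(3.2, 3.2))
  expect_error(hpd_interval(numeric(0)), "no draws")
  expect_error(hpd_interval(u, 1.2), "mass")
})

test_that("excludes_zero compares the lower bound to delta", {
  expect_true(excludes_zero(structure(list(lo = 0.01, hi = 0.2, mass = 0.95),
                                      class = "hpd_interval"), 1e-3))
  expect_false(excludes_zero(structure(list(lo = 5e-4, hi = 0.2, mass = 0.95),
                                       class = "hpd_interval"), 1e-3))
})

test_that("marginal rate draws behave like the beta layer at the bulk mean", {
  sc <- simulate_scenario(preset_scenarios(seed = 41)[["high-var"]])
  post <- run_sampler(sc, settings = quick_settings(42))
  set.seed(43)
  mr <- marginal_rate_draws(post)
  expect_true(all(mr >= 0 & mr <= 1))
  expect_equal(mean(mr), post$p_hat, tolerance = 0.03)
  # high variance => mass piles near the support edges (fat tails)
  expect_gt(mean(mr < 0.1 | mr > 0.9), 0.5)

  # v ~ 0 collapses the predictive onto the bulk mean
  post$v <- rep(1e-15, 100)
  expect_true(all(abs(marginal_rate_draws(post) - post$p_hat) < 1e-6))
})

test_that("beta-kernel density integrates to one and tracks a known density", {
  set.seed(7)
  draws <- rbeta(1e5, 2, 2)
  grid <- seq(0, 1, length.out = 101)
  kd <- beta_kernel_density(draws, grid)
  trap <- sum(diff(grid) * (head(kd$y, -1) + kd$y[-1]) / 2)
  expect_equal(trap, 1, tolerance = 0.02)
  expect_lt(max(abs(kd$y - dbeta(grid, 2, 2))), 0.05)
  expect_error(beta_kernel_density(numeric(0)), "no draws")
  expect_error(beta_kernel_density(c(0.5, 1.2)), "\\[0, 1\\]")
})
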