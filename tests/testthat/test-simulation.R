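test_that("built-in covariance conditions imply the labelled ICCs", {
  # arithmetic oracles: slope variance / (slope + residual variance)
  expect_equal(implied_icc(sim_sigma(0.05), 1229.93), 63.74 / 1293.67,
               tolerance = 1e-12)
  expect_equal(implied_icc(sim_sigma(0.30), 1229.93), 527.11 / 1757.04,
               tolerance = 1e-12)
  expect_equal(implied_icc(sim_sigma(0.50), 1229.93), 0.5, tolerance = 1e-12)
  expect_equal(round(implied_icc(sim_sigma(0.05), 1229.93), 2), 0.05)
  expect_equal(round(implied_icc(sim_sigma(0.30), 1229.93), 2), 0.30)
  expect_error(implied_icc(matrix(c(1, 0, 0, 0), 2), 1), "positive")
})

test_that("intercept-slope correlation is about -.33 in all conditions", {
  for (icc in c(0.05, 0.30, 0.50)) {
    S <- sim_sigma(icc)
    expect_equal(round(implied_re_correlation(S), 2), -0.33, info = icc)
    expect_equal(implied_re_correlation(S),
                 S[1, 2] / sqrt(S[1, 1] * S[2, 2]), tolerance = 1e-15)
  }
  expect_identical(implied_re_correlation(diag(c(2, 3))), 0)
  expect_error(sim_sigma(0.17), "built-in")
})

test_that("balanced datasets have 4 occasions at t = 0..3 per subject", {
  cfg <- sim_config(N = 16, icc = 0.05, replications = 1, seed = 1)
  d <- simulate_dataset(cfg, seed = 3)
  expect_equal(nrow(d), 64L)
  expect_equal(n_clusters(d), 16L)
  expect_true(all(vapply(split(d$time, d$id), function(t)
    identical(sort(t), 0:3), logical(1))))
  # exactly ceiling(N/2) subjects in group 1, group constant in subject
  per_subj <- vapply(split(d$group, d$id), unique, numeric(1))
  expect_equal(sum(per_subj), 8)
})

test_that("unbalanced datasets have t=0 plus 1-3 distinct follow-ups", {
  cfg <- sim_config(N = 20, icc = 0.30, balanced = FALSE, seed = 2)
  for (s in 1:3) {
    d <- simulate_dataset(cfg, seed = s)
    expect_gte(nrow(d), 2 * 20)
    expect_lte(nrow(d), 4 * 20)
    for (tt in split(d$time, d$id)) {
      expect_identical(tt[1], 0L)
      expect_true(all(tt[-1] %in% 1:3))
      expect_false(anyDuplicated(tt) > 0)
      expect_gte(length(tt), 2L)
      expect_lte(length(tt), 4L)
    }
  }
})

test_that("the noiseless limit recovers the generating curve exactly", {
  cfg <- sim_config(N = 8, Sigma = matrix(0, 2, 2), sigma_sq_eps = 0,
                    replications = 1, seed = 1)
  d <- simulate_dataset(cfg, seed = 5)
  expect_equal(d$y, 167.46 + 5.54 * d$group * d$time, tolerance = 1e-12)
  # noiseless estimates are exact: bias 0, and the degenerate parametric
  # interval (a point at the truth) covers the generating value
  des <- build_design(d, y ~ group * time)
  fr <- fit_glm(des$X, des$y)
  expect_equal(unname(fr$coefficients), c(167.46, 0, 0, 5.54),
               tolerance = 1e-8)
  out <- run_condition(sim_config(N = 8, Sigma = matrix(0, 2, 2),
                                  sigma_sq_eps = 0, replications = 3,
                                  seed = 4),
                       bootstrap = FALSE)
  bias <- out$metrics[out$metrics$metric == "bias", "value"]
  expect_equal(bias, rep(0, 4), tolerance = 1e-8)
})

test_that("invalid covariance specifications are fatal", {
  expect_error(sim_config(N = 8, Sigma = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
  expect_error(sim_config(N = 8, Sigma = matrix(c(1, 2, 3, 4), 2)),
               "symmetric")
})

test_that("proportion intervals match transcribed textbook formulas", {
  # Wilson at x=10, n=20
  got <- proportion_ci(10, 20, 0.95, method = "wilson")
  z <- qnorm(0.975)
  p <- 0.5
  n <- 20
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  expect_equal(unname(got), c(center - half, center + half),
               tolerance = 1e-10)

  # Agresti-Coull at x=42, n=100
  got2 <- proportion_ci(42, 100, 0.95, method = "agresti_coull")
  ntil <- 100 + z^2
  ptil <- (42 + z^2 / 2) / ntil
  half2 <- z * sqrt(ptil * (1 - ptil) / ntil)
  expect_equal(unname(got2), c(ptil - half2, ptil + half2),
               tolerance = 1e-10)

  # boundary: all successes has upper limit 1
  expect_equal(unname(proportion_ci(20, 20, 0.95, "wilson")["upper"]), 1,
               tolerance = 1e-12)
  # auto switches at the n = 40 threshold
  expect_equal(proportion_ci(10, 40, method = "auto"),
               proportion_ci(10, 40, method = "wilson"))
  expect_equal(proportion_ci(10, 41, method = "auto"),
               proportion_ci(10, 41, method = "agresti_coull"))
  expect_error(proportion_ci(0, 0), "positive")
})

test_that("per-subject slope variability ranks with the ICC condition", {
  set.seed(66)
  slope_spread <- vapply(c(0.05, 0.30, 0.50), function(icc) {
    cfg <- sim_config(N = 150, icc = icc, seed = 1)
    d <- simulate_dataset(cfg)
    slopes <- vapply(split(seq_len(nrow(d)), d$id), function(rows) {
      ols_oracle(cbind(1, d$time[rows]), d$y[rows])[2]
    }, numeric(1))
    var(slopes)
  }, numeric(1))
  expect_true(all(diff(slope_spread) > 0))
})

test_that("run_condition aggregates metrics and is seed-deterministic", {
  cfg <- sim_config(N = 12, icc = 0.05, replications = 4, B = 99, seed = 7)
  out1 <- run_condition(cfg)
  out2 <- run_condition(cfg)
  expect_identical(out1$metrics, out2$metrics)
  rates <- out1$metrics[out1$metrics$metric %in%
                          c("type_I", "power", "coverage"), ]
  expect_true(all(rates$value >= 0 & rates$value <= 1))
  expect_true(all(rates$lower <= rates$value & rates$value <= rates$upper))
  expect_true(all(rates$n <= 4))
  # point-estimate mode reports means and bias only
  fast <- run_condition(cfg, bootstrap = FALSE)
  expect_setequal(unique(fast$metrics$metric), c("mean_estimate", "bias"))
})

test_that("a small condition grid is tidy and complete", {
  grid <- run_simulation_grid(N = 12, icc = c(0.05, 0.50),
                              balanced = c(TRUE, FALSE),
                              replications = 2, B = 49, seed = 3)
  expect_equal(length(unique(interaction(grid$N, grid$icc, grid$balanced))),
               4L)
  expect_true(all(c("metric", "coefficient", "value", "n") %in% names(grid)))
})
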