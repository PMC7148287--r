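test_that("parametric interval matches the hand-computed SD oracle", {
  fit <- fake_fit(cbind(b = c(1, 2, 3)), c(b = 2))
  tab <- parametric_interval(fit, level = 0.95)
  z <- qnorm(0.975)
  # sample SD of {1,2,3} is exactly 1
  expect_equal(tab$boot_sd, 1, tolerance = 1e-15)
  expect_equal(tab$lower, 2 - z, tolerance = 1e-12)
  expect_equal(tab$upper, 2 + z, tolerance = 1e-12)
  # centered at the original estimate, symmetric
  expect_equal(tab$upper - tab$estimate, tab$estimate - tab$lower,
               tolerance = 1e-12)

  # zero bootstrap variance collapses to a point
  fit0 <- fake_fit(cbind(b = rep(5.5, 10)), c(b = 5.5))
  tab0 <- parametric_interval(fit0)
  expect_equal(tab0$lower, 5.5)
  expect_equal(tab0$upper, 5.5)
})

test_that("percentile ranks follow the order-statistic formula", {
  expect_identical(unname(percentile_ranks(5000, 0.95)), c(125, 4875))
  expect_identical(unname(percentile_ranks(4, 0.5)), c(1, 3))
  fit <- fake_fit(cbind(b = c(4, 2, 1, 3)), c(b = 2.5))
  tab <- suppressWarnings(percentile_interval(fit, level = 0.5))
  expect_equal(tab$lower, 1)
  expect_equal(tab$upper, 3)

  fitc <- fake_fit(cbind(b = rep(7, 50)), c(b = 7))
  tabc <- percentile_interval(fitc, level = 0.95)
  expect_equal(c(tabc$lower, tabc$upper), c(7, 7))
})

test_that("clustered jackknife rows equal direct leave-one-cluster-out refits", {
  d <- gaussian_toy()
  jack <- cluster_jackknife(y ~ x, d)
  expect_equal(nrow(jack), 5L)
  for (i in seq_len(5)) {
    keep <- as.data.frame(d)[d$id != cluster_ids(d)[i], ]
    des <- build_design(keep, y ~ x)
    expect_equal(unname(jack[i, ]), ols_oracle(des$X, des$y),
                 tolerance = 1e-10)
  }
  # exactly n refits, needs >= 3 clusters
  d3 <- clustered_data(data.frame(id = rep(1:3, each = 3),
                                  x = rnorm(9), y = rnorm(9)), "id")
  expect_equal(nrow(cluster_jackknife(y ~ x, d3)), 3L)
  d2 <- clustered_data(data.frame(id = rep(1:2, each = 3),
                                  x = rnorm(6), y = rnorm(6)), "id")
  expect_error(cluster_jackknife(y ~ x, d2), "3 clusters")
})

test_that("acceleration factor properties", {
  th <- c(0.2, -1.1, 0.7, 2.3, 0.05, -0.4, 1.9, 0.6)
  a <- glmcb:::bca_acceleration(th)
  # transcription of the cubed-deviation ratio
  dlt <- mean(th) - th
  expect_equal(a, sum(dlt^3) / (6 * sum(dlt^2)^1.5), tolerance = 1e-15)
  # location/scale invariance
  expect_equal(glmcb:::bca_acceleration(3.7 * th - 11), a, tolerance = 1e-12)
  # no jackknife variation means no acceleration
  expect_identical(glmcb:::bca_acceleration(rep(1.3, 6)), 0)
})

test_that("BCa collapses to the percentile interval when z0 = a = 0", {
  set.seed(4)
  b <- sort(rnorm(1000))
  est <- (b[500] + b[501]) / 2   # exactly half the estimates below
  jack <- cbind(b = c(1, 2, 3))  # symmetric jackknife: a = 0
  fit <- fake_fit(cbind(b = b), c(b = est), jackknife = jack)
  bca <- bca_interval(fit, level = 0.95)
  expect_equal(bca$z0, 0)
  expect_equal(bca$accel, 0)
  pct <- percentile_interval(fit, level = 0.95)
  expect_identical(bca$lower, pct$lower)
  expect_identical(bca$upper, pct$upper)
})

test_that("BCa endpoints match a step-by-step formula oracle", {
  set.seed(99)
  b <- rnorm(1000, 1, 2)
  est <- 0.8
  jack <- cbind(b = rnorm(8, 1, 0.5))
  fit <- fake_fit(cbind(b = b), c(b = est), jackknife = jack)
  level <- 0.95
  tab <- bca_interval(fit, level = level)
  # literal transcription, step by step
  z0 <- qnorm(sum(b < est) / 1000)
  dlt <- mean(jack[, 1]) - jack[, 1]
  a <- sum(dlt^3) / (6 * sum(dlt^2)^1.5)
  alpha <- 1 - level
  expected <- vapply(c(alpha / 2, 1 - alpha / 2), function(q) {
    zq <- qnorm(q)
    r <- floor(1000 * pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq))) + 0.5)
    sort(b)[min(max(r, 1), 1000)]
  }, numeric(1))
  expect_identical(c(tab$lower, tab$upper), expected)
  expect_equal(tab$z0, z0)
  expect_equal(tab$accel, a)
})

test_that("one-sided bootstrap distributions yield a missing BCa interval", {
  fit <- fake_fit(cbind(b = 1:20 / 10), c(b = 0),  # all estimates above
                  jackknife = cbind(b = rnorm(5)))
  expect_warning(tab <- bca_interval(fit), "one side")
  expect_true(is.na(tab$lower) && is.na(tab$upper))
})

test_that("intervals nest with increasing level (parametric, percentile)", {
  d <- gaussian_medium()
  fit <- cluster_bootstrap(y ~ x, d, B = 400, seed = 31)
  for (type in c("parametric", "percentile")) {
    narrow <- confint(fit, level = 0.90, type = type)
    wide <- confint(fit, level = 0.99, type = type)
    expect_true(all(wide$lower <= narrow$lower))
    expect_true(all(wide$upper >= narrow$upper))
  }
})

test_that("post-hoc recomputation never refits and subsets by name", {
  d <- gaussian_medium()
  fit <- cluster_bootstrap(y ~ x + z, d, B = 300, seed = 17)
  t1 <- confint(fit, level = 0.90, type = "parametric",
                parm = c("x", "z"))
  expect_equal(nrow(t1), 2L)
  expect_identical(rownames(t1), c("x", "z"))
  # idempotent at identical settings
  t2 <- confint(fit, level = 0.90, type = "parametric", parm = c("x", "z"))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_error(confint(fit, parm = "nope"), "available")
  # default type/level come from fit time
  tdef <- confint(fit)
  expect_identical(attr(tdef, "interval_type"), "BCa")
  expect_identical(attr(tdef, "level"), 0.95)
})

test_that("B_eff varies per coefficient when samples fail", {
  d <- rare_logistic()
  fit <- cluster_bootstrap(y ~ x, d, family = "binomial", B = 120, seed = 6)
  tab <- parametric_interval(fit)
  expect_true(all(tab$B_eff == 120 - failed_counts(fit)))
})
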