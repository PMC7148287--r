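#' Built-in random-effects covariance matrices
#'
#' The three 2x2 covariance matrices of the subject-level random
#' intercept and random slope used by the Monte Carlo design, labelled by
#' the intraclass correlation of the random slope: with residual variance
#' 1229.93, the slope variances 63.74, 527.11 and 1229.93 give slope ICCs
#' of .05, .30 and .50, while the intercept variance (2111.33) and the
#' intercept-slope correlation (about -.33) are held constant.
#'
#' @param icc One of `0.05`, `0.30`, `0.50`.
#' @return A symmetric 2x2 matrix.
#' @export
sim_sigma <- function(icc) {
  key <- sprintf("%.2f", icc)
  m <- switch(key,
              "0.05" = c(2111.33, -121.62, -121.62, 63.74),
              "0.30" = c(2111.33, -349.74, -349.74, 527.11),
              "0.50" = c(2111.33, -534.24, -534.24, 1229.93),
              stop("no built-in covariance for ICC = ", icc,
                   "; use 0.05, 0.30 or 0.50 or supply `Sigma` directly"))
  matrix(m, 2L, 2L)
}

#' Monte Carlo simulation configuration
#'
#' Describes one cell of the validation design. Data are generated from
#' the two-level linear growth model
#' `Y_ti = b0 + b1 G_i + b2 T_ti + b3 G_i T_ti + U_0i + U_1i T_ti + e_ti`
#' with subject random effects `(U_0i, U_1i) ~ MVN(0, Sigma)` and
#' residuals `e_ti ~ N(0, sigma_sq_eps)`. The default fixed effects set
#' the group (`b1`) and time (`b2`) effects to zero — so the time
#' coefficient measures type-I error — and the intercept and
#' group-by-time interaction to 167.46 and 5.54.
#'
#' @param N Number of subjects (the design uses 16, 32 or 64).
#' @param icc Slope ICC selecting a built-in `Sigma` (.05, .30 or .50).
#' @param balanced Balanced (four occasions at t = 0..3 per subject) or
#'   unbalanced (t = 0 plus 1-3 follow-ups at distinct integer times in
#'   1..3).
#' @param beta Fixed effects `(b0, b1, b2, b3)`.
#' @param sigma_sq_eps Residual variance.
#' @param Sigma Random-effects covariance; default `sim_sigma(icc)`.
#' @param replications Number of Monte Carlo replications (default 200).
#' @param B Bootstrap samples per replication (the design uses 5000;
#'   scaled-down runs use less).
#' @param level Confidence level (default 0.95).
#' @param seed Master seed; per-replication seeds are drawn from it up
#'   front so any single replication can be re-run in isolation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(N, icc = 0.05, balanced = TRUE,
                       beta = c(167.46, 0, 0, 5.54),
                       sigma_sq_eps = 1229.93,
                       Sigma = sim_sigma(icc),
                       replications = 200L, B = 5000L,
                       level = 0.95, seed = 1L) {
  if (N < 2) stop("`N` must be >= 2")
  if (length(beta) != 4L) stop("`beta` must have length 4")
  Sigma <- as.matrix(Sigma)
  if (!isTRUE(all.equal(Sigma, t(Sigma))))
    stop("`Sigma` must be symmetric")
  if (!all(Sigma == 0) && any(eigen(Sigma, symmetric = TRUE,
                                    only.values = TRUE)$values <= 0))
    stop("`Sigma` must be positive-definite (or all zero)")
  structure(list(N = as.integer(N), icc = icc, balanced = balanced,
                 beta = beta, sigma_sq_eps = sigma_sq_eps, Sigma = Sigma,
                 replications = as.integer(replications), B = as.integer(B),
                 level = level, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one clustered dataset from the generating model
#'
#' @param config A [sim_config()].
#' @param seed Optional seed for this replicate.
#' @return A [clustered_data] with columns `id`, `group` (0/1, exactly
#'   `ceiling(N/2)` subjects in group 1), `time`, and `y`.
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  N <- config$N
  G <- as.numeric(seq_len(N) <= ceiling(N / 2))
  if (all(config$Sigma == 0)) {
    U <- matrix(0, N, 2L)
  } else {
    U <- matrix(stats::rnorm(2L * N), N, 2L) %*% chol(config$Sigma)
  }
  times <- if (config$balanced) {
    rep(list(0:3), N)
  } else {
    lapply(seq_len(N), function(i) {
      k <- sample.int(3L, 1L)
      c(0L, sort(sample.int(3L, k)))
    })
  }
  nobs <- lengths(times)
  id <- rep(seq_len(N), nobs)
  t <- unlist(times, use.names = FALSE)
  g <- G[id]
  eps <- stats::rnorm(length(t), 0, sqrt(config$sigma_sq_eps))
  b <- config$beta
  y <- b[1L] + b[2L] * g + b[3L] * t + b[4L] * g * t +
    U[id, 1L] + U[id, 2L] * t + eps
  clustered_data(data.frame(id = id, group = g, time = t, y = y), "id")
}

#' Slope ICC implied by a random-effects covariance
#'
#' The share of the random-slope variance in the total slope-level
#' variance: `Sigma[2,2] / (Sigma[2,2] + sigma_sq_eps)`.
#'
#' @param Sigma 2x2 random-effects covariance.
#' @param sigma_sq_eps Residual variance.
#' @return A proportion in (0, 1).
#' @export
implied_icc <- function(Sigma, sigma_sq_eps) {
  s22 <- as.matrix(Sigma)[2L, 2L]
  if (s22 <= 0 || sigma_sq_eps <= 0)
    stop("variances must be positive")
  s22 / (s22 + sigma_sq_eps)
}

#' Intercept-slope correlation implied by a covariance matrix
#'
#' @param Sigma 2x2 random-effects covariance.
#' @return `Sigma[1,2] / sqrt(Sigma[1,1] * Sigma[2,2])`.
#' @export
implied_re_correlation <- function(Sigma) {
  S <- as.matrix(Sigma)
  if (any(diag(S) <= 0)) stop("diagonal of `Sigma` must be positive")
  S[1L, 2L] / sqrt(S[1L, 1L] * S[2L, 2L])
}

#' Binomial proportion confidence interval
#'
#' Score-based intervals for Monte Carlo rates: Agresti-Coull by default,
#' Wilson when the denominator is 40 or less (`method = "auto"`).
#'
#' @param successes Number of successes (0..n).
#' @param n Denominator (> 0).
#' @param level Confidence level.
#' @param method `"auto"`, `"agresti_coull"`, or `"wilson"`.
#' @return Named numeric vector `c(lower, upper)`, clamped to `[0, 1]`.
#' @export
proportion_ci <- function(successes, n, level = 0.95,
                          method = c("auto", "agresti_coull", "wilson")) {
  method <- match.arg(method)
  if (length(n) != 1L || is.na(n) || n <= 0) stop("`n` must be positive")
  if (successes < 0 || successes > n)
    stop("`successes` must be in 0..n")
  if (method == "auto") method <- if (n <= 40) "wilson" else "agresti_coull"
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wilson") {
    phat <- successes / n
    denom <- 1 + z^2 / n
    center <- (phat + z^2 / (2 * n)) / denom
    half <- (z / denom) * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  } else {
    ntil <- n + z^2
    ptil <- (successes + z^2 / 2) / ntil
    center <- ptil
    half <- z * sqrt(ptil * (1 - ptil) / ntil)
  }
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Run one Monte Carlo condition
#'
#' For each replication: simulate a dataset from the generating model,
#' fit the gaussian GLM `y ~ group * time` (with the balanced cluster
#' bootstrap and a BCa interval unless `bootstrap = FALSE`), and record
#' the time (`b2`) and group-by-time (`b3`) estimates, whether zero is
#' excluded from their intervals, and whether the generating values are
#' covered. Aggregates follow the printed definitions: bias is the mean
#' estimation error over replications; the type-I rate (for the null
#' `b2`) is the fraction of replications whose interval excludes zero;
#' power (for `b3`) additionally requires the estimate's sign to match
#' the generating effect; coverage is the fraction of intervals
#' containing the generating value. Every rate carries an Agresti-Coull
#' (or Wilson, for denominators of at most 40) confidence band.
#'
#' @param config A [sim_config()].
#' @param bootstrap If `FALSE`, only GLM point estimates are computed
#'   (no intervals): enough for bias and parameter-recovery summaries,
#'   and orders of magnitude faster.
#' @param n_workers Workers passed to [cluster_bootstrap()].
#' @param verbose Print a progress line every 50 replications.
#' @return A list of class `glmcb_sim`: `config`, `estimates`
#'   (replications x 4 matrix), `metrics` (tidy data frame with columns
#'   metric, coefficient, value, lower, upper, n), and `seeds`.
#' @export
run_condition <- function(config, bootstrap = TRUE, n_workers = 1L,
                          verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  R <- config$replications
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max, 2L * R), R, 2L)
  est <- matrix(NA_real_, R, 4L)
  lo <- up <- matrix(NA_real_, R, 2L,
                     dimnames = list(NULL, c("time", "group:time")))
  ok <- logical(R)
  for (r in seq_len(R)) {
    d <- simulate_dataset(config, seed = seeds[r, 1L])
    if (bootstrap) {
      fit <- tryCatch(
        cluster_bootstrap(y ~ group * time, d, family = stats::gaussian(),
                          B = config$B, level = config$level,
                          interval_type = "BCa", seed = seeds[r, 2L],
                          n_workers = n_workers),
        error = function(e) NULL)
      if (is.null(fit)) next
      est[r, ] <- fit$original$coefficients
      ci <- bca_interval(fit)
      lo[r, ] <- ci[c("time", "group:time"), "lower"]
      up[r, ] <- ci[c("time", "group:time"), "upper"]
      ok[r] <- !anyNA(c(lo[r, ], up[r, ]))
    } else {
      des <- build_design(d, y ~ group * time)
      fr <- fit_glm(des$X, des$y)
      if (fr$failure_code != "none") next
      est[r, ] <- fr$coefficients
      ok[r] <- TRUE
    }
    if (verbose && r %% 50L == 0L)
      message("replication ", r, "/", R)
  }
  colnames(est) <- c("(Intercept)", "group", "time", "group:time")
  metrics <- aggregate_metrics(config, est, lo, up, ok, bootstrap)
  structure(list(config = config, estimates = est,
                 lower = lo, upper = up, completed = ok,
                 metrics = metrics, seeds = seeds),
            class = "glmcb_sim")
}

aggregate_metrics <- function(config, est, lo, up, ok, bootstrap) {
  b <- config$beta
  truth <- c("(Intercept)" = b[1L], "group" = b[2L],
             "time" = b[3L], "group:time" = b[4L])
  have_est <- !is.na(est[, 1L])
  rows <- list()
  add <- function(metric, coefficient, value, n, band = NULL) {
    if (is.null(band)) band <- c(lower = NA_real_, upper = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, coefficient = coefficient, value = value,
      lower = band[["lower"]], upper = band[["upper"]], n = n)
  }
  for (cf in names(truth)) {
    add("mean_estimate", cf, mean(est[have_est, cf]), sum(have_est))
    add("bias", cf, mean(est[have_est, cf] - truth[cf]), sum(have_est))
  }
  if (bootstrap) {
    n <- sum(ok)
    if (n > 0L) {
      sig2 <- lo[ok, "time"] > 0 | up[ok, "time"] < 0
      add("type_I", "time", mean(sig2), n,
          proportion_ci(sum(sig2), n, config$level))
      sig3 <- (lo[ok, "group:time"] > 0 | up[ok, "group:time"] < 0) &
        sign(est[ok, "group:time"]) == sign(truth["group:time"])
      add("power", "group:time", mean(sig3), n,
          proportion_ci(sum(sig3), n, config$level))
      for (cf in c("time", "group:time")) {
        cov <- lo[ok, cf] <= truth[cf] & truth[cf] <= up[ok, cf]
        add("coverage", cf, mean(cov), n,
            proportion_ci(sum(cov), n, config$level))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.glmcb_sim <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat("Monte Carlo condition: N = ", cfg$N, ", slope ICC = ", cfg$icc,
      ", ", if (cfg$balanced) "balanced" else "unbalanced",
      ", replications = ", cfg$replications, "\n\n", sep = "")
  print(signif_df(x$metrics, digits))
  invisible(x)
}

#' Run a grid of Monte Carlo conditions
#'
#' Expands `N x icc x balanced` into conditions, runs each with
#' [run_condition()], and returns one tidy data frame (one row per
#' condition, coefficient and metric).
#'
#' @param N,icc,balanced Vectors of condition levels.
#' @param replications,B,level,seed,bootstrap,n_workers Passed through to
#'   [sim_config()] / [run_condition()]; each condition gets a distinct
#'   seed derived from `seed`.
#' @return A data frame with condition columns prepended to the metrics.
#' @export
run_simulation_grid <- function(N = c(16L, 32L, 64L),
                                icc = c(0.05, 0.30, 0.50),
                                balanced = c(TRUE, FALSE),
                                replications = 200L, B = 5000L,
                                level = 0.95, seed = 1L,
                                bootstrap = TRUE, n_workers = 1L) {
  grid <- expand.grid(N = N, icc = icc, balanced = balanced,
                      KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- sim_config(N = grid$N[i], icc = grid$icc[i],
                      balanced = grid$balanced[i],
                      replications = replications, B = B, level = level,
                      seed = seed + i - 1L)
    m <- run_condition(cfg, bootstrap = bootstrap, n_workers = n_workers)$metrics
    cbind(grid[rep(i, nrow(m)), , drop = FALSE], m, row.names = NULL)
  })
  do.call(rbind, out)
}
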