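# Deterministic fixtures shared across test files.

# gaussian toy: 5 clusters x 2 rows, fixed numbers
gaussian_toy <- function() {
  clustered_data(data.frame(
    id = rep(c("a", "b", "c", "d", "e"), each = 2),
    x  = c(0.0, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0, 4.5),
    y  = c(1.2, 0.8, 2.1, 2.9, 3.3, 4.1, 4.8, 5.9, 6.2, 7.4)), "id")
}

# clustered gaussian data with enough clusters for bootstrap tests
gaussian_medium <- function(n_clusters = 12L, rows_per = 3L, seed = 42L) {
  set.seed(seed)
  n <- n_clusters * rows_per
  clustered_data(data.frame(
    id = rep(seq_len(n_clusters), each = rows_per),
    x = rnorm(n),
    z = rep(rnorm(n_clusters), each = rows_per),
    y = rnorm(n)), "id")
}

# logistic fixture whose successes all sit in two clusters, so bootstrap
# samples that miss both clusters have a constant (all-zero) response
rare_logistic <- function(n_clusters = 10L, rows_per = 4L) {
  d <- data.frame(
    id = rep(seq_len(n_clusters), each = rows_per),
    x = rep(seq_len(rows_per) - 1, n_clusters),
    y = 0)
  d$y[d$id <= 2L & d$x >= 2] <- 1
  clustered_data(d, "id")
}

# minimal glmcb-shaped object for interval arithmetic tests
fake_fit <- function(coefmat, original, level = 0.95, jackknife = NULL) {
  structure(list(coefficients = coefmat,
                 original = list(coefficients = original),
                 jackknife = jackknife,
                 B = nrow(coefmat), level = level,
                 interval_type = "BCa"),
            class = "glmcb")
}

# independent OLS oracle: normal equations
ols_oracle <- function(X, y) {
  as.vector(solve(crossprod(X), crossprod(X, y)))
}
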