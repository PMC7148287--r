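#' Generalized linear model with the balanced cluster bootstrap
#'
#' Fits the GLM to the parent data, then refits it to `B` balanced
#' cluster-bootstrap samples: whole clusters are resampled so that the
#' within-cluster dependency is preserved in every sample, and the
#' balanced scheme guarantees each cluster enters exactly `B` times over
#' the `B` samples. All randomness is exhausted up front by the index
#' matrix; the refits themselves are deterministic, so results are
#' bit-identical for any number of workers under a fixed seed.
#'
#' @param formula Model formula, e.g. `pos ~ treat * time`.
#' @param data Long-format data frame or [clustered_data] object.
#' @param cluster Name of the cluster-identifier column (ignored when
#'   `data` is already a `clustered_data`). For non-clustered data a
#'   per-row unique key makes this an ordinary pairs bootstrap.
#' @param family Error distribution / link, see [resolve_family()].
#'   Default gaussian/identity.
#' @param B Number of bootstrap samples (default 5000).
#' @param level Confidence level in (0, 1) (default 0.95).
#' @param interval_type Default interval for `summary()`: `"BCa"`
#'   (default), `"percentile"`, or `"parametric"`.
#' @param seed Integer seed driving the balanced index matrix.
#' @param n_workers Number of parallel workers for the refits (default 1).
#' @param controls See [glm_controls()].
#' @param keep_nonconverged Keep divergent coefficients of non-converged
#'   refits in the bootstrap distribution instead of recording `NA`.
#' @return An object of class `glmcb` with, among others, elements
#'   `coefficients` (B x p matrix of bootstrap estimates, `NA` where a
#'   refit failed), `original` (the parent-fit result), `indices` (N x B
#'   cluster index matrix), `jackknife` (leave-one-cluster-out estimates,
#'   used by the BCa interval), `samples_with_NA_coef` and
#'   `failed_bootstrap_samples`.
#' @examples
#' d <- data.frame(id = rep(1:10, each = 3),
#'                 x = rnorm(30), y = rnorm(30))
#' fit <- cluster_bootstrap(y ~ x, d, cluster = "id", B = 99, seed = 1)
#' summary(fit)
#' @export
cluster_bootstrap <- function(formula, data, cluster = NULL,
                              family = stats::gaussian(), B = 5000L,
                              level = 0.95,
                              interval_type = c("BCa", "percentile", "parametric"),
                              seed = NULL, n_workers = 1L,
                              controls = glm_controls(),
                              keep_nonconverged = FALSE) {
  interval_type <- match.arg(interval_type)
  if (B < 1) stop("`B` must be >= 1")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  if (!inherits(data, "clustered_data")) {
    if (is.null(cluster)) stop("`cluster` must name the cluster-id column")
    data <- clustered_data(data, cluster)
  }
  N <- n_clusters(data)
  if (N < 2L) stop("at least 2 clusters are required (found ", N, ")")
  fam <- resolve_family(family)

  design <- build_design(data, formula)
  X <- design$X
  y <- design$y
  p <- ncol(X)

  original <- fit_glm(X, y, fam, controls)
  if (original$failure_code != "none")
    stop("GLM fit on the parent data failed (", original$failure_code,
         "); not bootstrapping")

  rows <- cluster_rows(data)
  indices <- build_balanced_indices(N, B, seed)

  fit_one <- function(b) {
    ridx <- unlist(rows[indices[, b]], use.names = FALSE)
    fit_glm(X[ridx, , drop = FALSE], y[ridx], fam, controls,
            keep_coefficients = keep_nonconverged)$coefficients
  }
  if (n_workers > 1L) {
    res <- parallel::mclapply(seq_len(B), fit_one,
                              mc.cores = n_workers, mc.preschedule = TRUE)
    coefmat <- do.call(rbind, res)
  } else {
    coefmat <- t(vapply(seq_len(B), fit_one, numeric(p)))
  }
  colnames(coefmat) <- design$coef_names

  failed_ids <- which(apply(coefmat, 1L, anyNA))
  failed_counts <- as.integer(colSums(is.na(coefmat)))
  names(failed_counts) <- design$coef_names
  if (any(failed_counts == B))
    warning("all ", B, " bootstrap fits failed for coefficient(s): ",
            paste(design$coef_names[failed_counts == B], collapse = ", "))

  jack <- jackknife_matrix(X, y, rows, fam, controls)

  structure(list(
    call = match.call(),
    formula = formula,
    family = fam,
    data = data,
    design = design,
    original = original,
    coefficients = coefmat,
    indices = indices,
    jackknife = jack,
    B = as.integer(B),
    level = level,
    interval_type = interval_type,
    seed = seed,
    controls = controls,
    samples_with_NA_coef = as.integer(failed_ids),
    failed_bootstrap_samples = failed_counts
  ), class = "glmcb")
}

# leave-one-cluster-out coefficient matrix (n_clusters x p)
jackknife_matrix <- function(X, y, rows, fam, controls) {
  N <- length(rows)
  p <- ncol(X)
  out <- matrix(NA_real_, N, p, dimnames = list(names(rows), colnames(X)))
  for (i in seq_len(N)) {
    keep <- setdiff(seq_len(nrow(X)), rows[[i]])
    fr <- fit_glm(X[keep, , drop = FALSE], y[keep], fam, controls)
    if (fr$failure_code == "none") out[i, ] <- fr$coefficients
  }
  out
}

#' Reconstruct the dataset of one bootstrap sample
#'
#' Rebuilds, from the stored index matrix, the exact dataset that was
#' used for bootstrap sample `b` — typically to inspect a sample whose
#' GLM failed (constant response, separation, dropped factor level). The
#' result can be refitted standalone and reproduces row `b` of the
#' coefficient matrix (or its failure).
#'
#' @param fit A `glmcb` object.
#' @param b Bootstrap sample number in `1:B`.
#' @return A [clustered_data] object.
#' @export
get_bootstrap_sample <- function(fit, b) {
  stopifnot(inherits(fit, "glmcb"))
  if (length(b) != 1L || is.na(b) || b < 1L || b > fit$B)
    stop("`b` must be a single sample number in 1..", fit$B)
  materialize_sample(fit$data, fit$indices[, as.integer(b)])
}

#' Bootstrapped covariance matrix of the coefficient estimates
#'
#' Sample covariance of the bootstrap coefficient estimates over the
#' samples in which every coefficient was estimated (complete rows). The
#' diagonal holds the squared bootstrap standard errors over those rows.
#'
#' @param fit A `glmcb` object.
#' @return A symmetric p x p matrix.
#' @export
bootstrap_covariance <- function(fit) {
  stopifnot(inherits(fit, "glmcb"))
  cm <- fit$coefficients
  complete <- stats::complete.cases(cm)
  if (sum(complete) < 2L)
    stop("need >= 2 complete bootstrap samples for a covariance; have ",
         sum(complete))
  stats::cov(cm[complete, , drop = FALSE])
}
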