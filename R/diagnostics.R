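#' Extract coefficient estimates
#'
#' Either the per-coefficient means over the successful bootstrap samples
#' (the default, and the estimate column shown by `summary()`) or the
#' coefficients of the GLM fitted on the original data. The two usually
#' agree closely but not exactly; intervals are always anchored at the
#' original-sample estimate.
#'
#' @param object A `glmcb` object.
#' @param estimate_type `"bootstrap"` (bootstrap means, default) or
#'   `"GLM"` (original-sample fit).
#' @param ... Unused.
#' @return Named numeric vector of length p.
#' @export
coef.glmcb <- function(object, estimate_type = c("bootstrap", "GLM"), ...) {
  estimate_type <- match.arg(estimate_type)
  if (estimate_type == "GLM") return(object$original$coefficients)
  colMeans(object$coefficients, na.rm = TRUE)
}

#' Bootstrap samples in which the GLM failed
#'
#' `failed_samples()` returns the sorted 1-based sample numbers whose
#' refit produced at least one `NA` coefficient; `failed_counts()`
#' returns, per coefficient, how many of the B samples are missing it.
#' Equal counts across all coefficients indicate whole-fit failures
#' (constant response, nonconvergence); a count concentrated on one
#' dummy coefficient indicates its factor level was absent from those
#' samples.
#'
#' @param fit A `glmcb` object.
#' @return Integer vector (sample ids) / named integer vector (counts).
#' @export
failed_samples <- function(fit) {
  stopifnot(inherits(fit, "glmcb"))
  fit$samples_with_NA_coef
}

#' @rdname failed_samples
#' @export
failed_counts <- function(fit) {
  stopifnot(inherits(fit, "glmcb"))
  fit$failed_bootstrap_samples
}

#' @export
print.glmcb <- function(x, ...) {
  cat("Generalized linear model with the cluster bootstrap\n\nCall:\n")
  print(x$call)
  cat("\nFamily:", x$family$family, "(link:", x$family$link, ")\n")
  cat("Clusters:", n_clusters(x$data), " Observations:", nrow(x$data),
      " Bootstrap samples:", x$B, "\n\nCoefficients (bootstrap means):\n")
  print(signif(coef(x), 4))
  invisible(x)
}

interval_footnote <- function(type, level) {
  lab <- switch(type,
                BCa = "bias corrected and accelerated cluster bootstrap",
                percentile = "percentile cluster bootstrap",
                parametric = "parametric cluster bootstrap")
  paste0(format(100 * level), "% confidence interval using ", lab,
         " intervals")
}

#' Summarize a cluster-bootstrap GLM
#'
#' One row per coefficient: the bootstrap-mean estimate, the
#' original-sample GLM estimate, the bootstrap standard deviation, and
#' the confidence bounds of the requested interval type. A footnote
#' states the interval type and level; when any bootstrap sample
#' returned an `NA` coefficient a notice reports how many.
#'
#' @param object A `glmcb` object.
#' @param interval_type Interval for the CI columns (default: the type
#'   chosen at fit time).
#' @param level Confidence level (default: the fit-time level).
#' @param ... Unused.
#' @return A `summary.glmcb` object (printable; the table is in `$table`).
#' @export
summary.glmcb <- function(object, interval_type = object$interval_type,
                          level = object$level, ...) {
  ci <- confint.glmcb(object, level = level, type = interval_type)
  a2 <- (1 - level) / 2
  tab <- data.frame(
    Estimate = ci$boot_mean,
    GLM = ci$estimate,
    `Std.error` = ci$boot_sd,
    lower = ci$lower,
    upper = ci$upper,
    check.names = FALSE,
    row.names = rownames(ci))
  names(tab)[4:5] <- paste0("CI ", format(100 * c(a2, 1 - a2)), "%")
  structure(list(call = object$call, table = tab,
                 footnote = interval_footnote(interval_type, level),
                 n_failed = length(object$samples_with_NA_coef),
                 B_eff = ci$B_eff, B = object$B),
            class = "summary.glmcb")
}

#' @export
print.summary.glmcb <- function(x, digits = 4, ...) {
  cat("Call:\n")
  print(x$call)
  cat("\n")
  print(signif_df(x$table, digits))
  cat("---\n", x$footnote, "\n", sep = "")
  if (any(x$B_eff < x$B))
    cat("Effective B per coefficient: ",
        paste(rownames(x$table), x$B_eff, sep = "=", collapse = ", "), "\n",
        sep = "")
  if (x$n_failed > 0L)
    cat("There were ", x$n_failed, " bootstrap samples which returned ",
        "at least one NA\n", sep = "")
  invisible(x)
}

#' Write fit artifacts to a directory
#'
#' Serializes a `glmcb` fit for audit or replay: the bootstrap
#' coefficient matrix and the cluster index matrix as CSV (full
#' precision), the model settings as JSON, and the text summary.
#'
#' @param fit A `glmcb` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_glmcb <- function(fit, dir) {
  stopifnot(inherits(fit, "glmcb"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    coefficients = file.path(dir, "coefficients.csv"),
    indices = file.path(dir, "index_matrix.csv"),
    intervals = file.path(dir, "intervals.csv"),
    failures = file.path(dir, "failed_samples.csv"),
    spec = file.path(dir, "spec.json"),
    summary = file.path(dir, "summary.txt"))
  utils::write.csv(fit$coefficients, paths["coefficients"], row.names = FALSE)
  utils::write.csv(fit$indices, paths["indices"], row.names = FALSE)
  ci <- confint.glmcb(fit)
  utils::write.csv(cbind(coefficient = rownames(ci), as.data.frame(ci)),
                   paths["intervals"], row.names = FALSE)
  utils::write.csv(data.frame(sample = fit$samples_with_NA_coef),
                   paths["failures"], row.names = FALSE)
  jsonlite::write_json(
    list(formula = deparse(fit$formula), family = fit$family$family,
         link = fit$family$link, B = fit$B, level = fit$level,
         interval_type = fit$interval_type, seed = fit$seed,
         n_clusters = n_clusters(fit$data),
         failed_counts = as.list(fit$failed_bootstrap_samples)),
    paths["spec"], auto_unbox = TRUE, digits = NA)
  writeLines(utils::capture.output(print(summary(fit))), paths["summary"])
  invisible(paths)
}
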