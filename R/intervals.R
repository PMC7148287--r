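new_interval_table <- function(df, type, level) {
  structure(df, interval_type = type, level = level,
            class = c("glmcb_intervals", "data.frame"))
}

#' @export
print.glmcb_intervals <- function(x, digits = 4, ...) {
  cat(format(100 * attr(x, "level")), "% ", attr(x, "interval_type"),
      " cluster bootstrap intervals\n", sep = "")
  print.data.frame(signif_df(x, digits))
  invisible(x)
}

signif_df <- function(df, digits) {
  as.data.frame(lapply(df, function(col)
    if (is.numeric(col)) signif(col, digits) else col),
    row.names = rownames(df), check.names = FALSE)
}

# per-coefficient vector of successful bootstrap estimates
boot_columns <- function(fit) {
  lapply(stats::setNames(seq_len(ncol(fit$coefficients)),
                         colnames(fit$coefficients)),
         function(j) fit$coefficients[!is.na(fit$coefficients[, j]), j])
}

#' Parametric (normal-theory) bootstrap interval
#'
#' The bootstrap standard deviation of each coefficient estimates its
#' standard error; the interval is the original-sample estimate plus or
#' minus the normal quantile times that standard error. Symmetric about
#' the original estimate by construction.
#'
#' @param fit A `glmcb` object.
#' @param level Confidence level (default: the level stored in `fit`).
#' @return A `glmcb_intervals` data frame with one row per coefficient:
#'   `estimate` (original-sample), `boot_mean`, `boot_sd`, `lower`,
#'   `upper`, `B_eff` (number of successful bootstrap samples).
#' @export
parametric_interval <- function(fit, level = fit$level) {
  stopifnot(inherits(fit, "glmcb"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  cols <- boot_columns(fit)
  est <- fit$original$coefficients
  tab <- do.call(rbind, lapply(names(cols), function(nm) {
    b <- cols[[nm]]
    if (length(b) < 2L) {
      warning("fewer than 2 successful bootstrap samples for '", nm,
              "'; interval reported missing")
      return(data.frame(estimate = est[nm], boot_mean = NA_real_,
                        boot_sd = NA_real_, lower = NA_real_,
                        upper = NA_real_, B_eff = length(b)))
    }
    s <- stats::sd(b)
    data.frame(estimate = est[nm], boot_mean = mean(b), boot_sd = s,
               lower = est[nm] - z * s, upper = est[nm] + z * s,
               B_eff = length(b))
  }))
  rownames(tab) <- names(cols)
  new_interval_table(tab, "parametric", level)
}

# order-statistic ranks of the percentile interval
percentile_ranks <- function(B_eff, level) {
  a2 <- (1 - level) / 2
  c(lower = max(1L, floor(B_eff * a2)),
    upper = min(B_eff, ceiling(B_eff * (1 - a2))))
}

#' Percentile bootstrap interval
#'
#' Rank-orders the successful bootstrap estimates of each coefficient and
#' reads the interval off the empirical distribution: with `B` = 5000 and
#' a 95% level, the endpoints are the 125th and 4875th order statistics.
#'
#' @inheritParams parametric_interval
#' @return A `glmcb_intervals` data frame, see [parametric_interval()].
#' @export
percentile_interval <- function(fit, level = fit$level) {
  stopifnot(inherits(fit, "glmcb"))
  cols <- boot_columns(fit)
  est <- fit$original$coefficients
  tab <- do.call(rbind, lapply(names(cols), function(nm) {
    b <- cols[[nm]]
    if (length(b) < 2 / (1 - level))
      warning("only ", length(b), " successful samples for '", nm,
              "': extreme order statistics at level ", level,
              " are unreliable")
    if (length(b) < 1L)
      return(data.frame(estimate = est[nm], boot_mean = NA_real_,
                        boot_sd = NA_real_, lower = NA_real_,
                        upper = NA_real_, B_eff = 0L))
    sb <- sort(b)
    r <- percentile_ranks(length(b), level)
    data.frame(estimate = est[nm], boot_mean = mean(b),
               boot_sd = if (length(b) > 1L) stats::sd(b) else NA_real_,
               lower = sb[r["lower"]], upper = sb[r["upper"]],
               B_eff = length(b))
  }))
  rownames(tab) <- names(cols)
  new_interval_table(tab, "percentile", level)
}

#' Leave-one-cluster-out jackknife estimates
#'
#' Refits the GLM n times, each time removing all rows of one cluster —
#' the clustered analogue of the ordinary jackknife, used to compute the
#' acceleration factor of the BCa interval.
#'
#' @param formula Model formula.
#' @param data Data frame or [clustered_data].
#' @param cluster Cluster-id column name (when `data` is a plain frame).
#' @param family Family spec.
#' @param controls See [glm_controls()].
#' @return An n_clusters x p matrix of coefficient estimates, one row per
#'   left-out cluster (rows of failed refits are `NA` and are excluded
#'   from the acceleration factor with a warning downstream).
#' @export
cluster_jackknife <- function(formula, data, cluster = NULL,
                              family = stats::gaussian(),
                              controls = glm_controls()) {
  if (!inherits(data, "clustered_data")) {
    if (is.null(cluster)) stop("`cluster` must name the cluster-id column")
    data <- clustered_data(data, cluster)
  }
  if (n_clusters(data) < 3L)
    stop("jackknife needs at least 3 clusters")
  design <- build_design(data, formula)
  jackknife_matrix(design$X, design$y, cluster_rows(data),
                   resolve_family(family), controls)
}

# BCa acceleration factor from one jackknife column; 0 when the jackknife
# estimates show no variation (limit of no acceleration)
bca_acceleration <- function(theta_jack) {
  th <- theta_jack[!is.na(theta_jack)]
  if (length(th) < 2L) return(NA_real_)
  d <- mean(th) - th
  denom <- 6 * sum(d^2)^1.5
  if (denom == 0) return(0)
  sum(d^3) / denom
}

# round half away from zero (ranks are positive, so round half up)
round_half_away <- function(x) floor(x + 0.5)

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Adjusts the percentile endpoints for median bias and for the rate of
#' change of the standard error. The bias-correction factor is
#' `z0 = qnorm(#(b* < b_hat) / B_eff)` — the normal quantile of the
#' proportion of bootstrap estimates strictly below the original estimate
#' (ties count as not-below) — and the acceleration factor `a` is the
#' cubed-deviation ratio over the leave-one-cluster-out jackknife
#' estimates. The endpoint ranks are
#' `B_eff * pnorm(z0 + (z0 + z_q) / (1 - a (z0 + z_q)))` for
#' `q = alpha/2` and `1 - alpha/2`, rounded half away from zero and
#' clamped to `[1, B_eff]`. When all bootstrap estimates lie on one side
#' of the original estimate, `z0` is infinite and the interval is
#' reported missing with a diagnostic rather than silently clamped.
#' With `z0 = 0` and `a = 0` the BCa ranks collapse to the percentile
#' ranks exactly.
#'
#' @inheritParams parametric_interval
#' @param jackknife Optional n x p jackknife matrix; defaults to the one
#'   stored in `fit`.
#' @return A `glmcb_intervals` data frame with additional columns `z0`
#'   and `accel`.
#' @export
bca_interval <- function(fit, level = fit$level, jackknife = fit$jackknife) {
  stopifnot(inherits(fit, "glmcb"))
  cols <- boot_columns(fit)
  est <- fit$original$coefficients
  a2 <- (1 - level) / 2
  tab <- do.call(rbind, lapply(names(cols), function(nm) {
    b <- cols[[nm]]
    B_eff <- length(b)
    row <- data.frame(estimate = est[nm],
                      boot_mean = if (B_eff) mean(b) else NA_real_,
                      boot_sd = if (B_eff > 1L) stats::sd(b) else NA_real_,
                      lower = NA_real_, upper = NA_real_,
                      z0 = NA_real_, accel = NA_real_, B_eff = B_eff)
    if (B_eff < 2L) {
      warning("fewer than 2 successful bootstrap samples for '", nm, "'")
      return(row)
    }
    prop <- sum(b < est[nm]) / B_eff
    if (prop <= 0 || prop >= 1) {
      warning("all bootstrap estimates for '", nm, "' lie on one side of ",
              "the original estimate (proportion below = ", prop,
              "); z0 is infinite and the BCa interval is undefined")
      return(row)
    }
    z0 <- stats::qnorm(prop)
    jk <- jackknife[, nm]
    if (anyNA(jk))
      warning(sum(is.na(jk)), " jackknife refit(s) failed for '", nm,
              "'; acceleration uses the remaining clusters")
    a <- bca_acceleration(jk)
    if (is.na(a)) {
      warning("acceleration factor unavailable for '", nm, "'")
      return(row)
    }
    sb <- sort(b)
    zq <- stats::qnorm(c(a2, 1 - a2))
    adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    ranks <- pmin(pmax(round_half_away(B_eff * adj), 1L), B_eff)
    row$lower <- sb[ranks[1L]]
    row$upper <- sb[ranks[2L]]
    row$z0 <- z0
    row$accel <- a
    row
  }))
  rownames(tab) <- names(cols)
  new_interval_table(tab, "BCa", level)
}

#' Recompute confidence intervals post hoc
#'
#' Changes the level, the interval type, or the set of coefficients of an
#' existing fit without redoing the bootstrap: only interval arithmetic
#' is rerun on the stored coefficient and jackknife matrices.
#'
#' @param object A `glmcb` object.
#' @param parm Coefficient names to keep (default: all).
#' @param level Confidence level.
#' @param type `"BCa"`, `"percentile"`, or `"parametric"` (default: the
#'   type chosen at fit time).
#' @param ... Unused.
#' @return A `glmcb_intervals` data frame restricted to `parm`.
#' @export
confint.glmcb <- function(object, parm = NULL, level = object$level,
                          type = object$interval_type, ...) {
  type <- match.arg(type, c("BCa", "percentile", "parametric"))
  tab <- switch(type,
                BCa = bca_interval(object, level),
                percentile = percentile_interval(object, level),
                parametric = parametric_interval(object, level))
  if (!is.null(parm)) {
    unknown <- setdiff(parm, rownames(tab))
    if (length(unknown) > 0L)
      stop("unknown coefficient(s): ", paste(unknown, collapse = ", "),
           "; available: ", paste(rownames(tab), collapse = ", "))
    tab <- new_interval_table(tab[parm, , drop = FALSE], type, level)
  }
  tab
}
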