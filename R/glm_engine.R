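#' Resolve a family/link specification
#'
#' Accepts a family object, a family function, or one of the supported
#' names: gaussian (identity), binomial (logit), poisson (log), Gamma,
#' inverse.gaussian, quasibinomial, quasipoisson.
#'
#' @param family Family object, function, or name.
#' @return A `stats::family` object.
#' @keywords internal
resolve_family <- function(family) {
  if (is.character(family)) {
    supported <- c("gaussian", "binomial", "poisson", "Gamma",
                   "inverse.gaussian", "quasibinomial", "quasipoisson")
    m <- supported[match(tolower(family), tolower(supported))]
    if (is.na(m)) stop("unsupported family '", family, "'; supported: ",
                       paste(supported, collapse = ", "))
    family <- get(m, mode = "function", envir = asNamespace("stats"))
  }
  if (is.function(family)) family <- family()
  if (!inherits(family, "family")) stop("invalid `family` specification")
  family
}

is_discrete_family <- function(fam) {
  fam$family %in% c("binomial", "quasibinomial", "poisson", "quasipoisson")
}

#' GLM fit controls
#'
#' @param epsilon Convergence tolerance on the relative deviance change.
#' @param maxit Maximum number of IRLS iterations.
#' @param separation_threshold Absolute coefficient size on the link scale
#'   beyond which a binomial-type fit is flagged as (quasi-)separated and
#'   treated as non-converged. Logistic coefficients this large imply odds
#'   ratios beyond any realistic effect and are the signature of a
#'   diverging likelihood.
#' @return A list of control settings.
#' @export
glm_controls <- function(epsilon = 1e-8, maxit = 25L, separation_threshold = 12) {
  list(epsilon = epsilon, maxit = as.integer(maxit),
       separation_threshold = separation_threshold)
}

#' Fit one GLM and report coefficients or a structured failure
#'
#' Fits by iteratively reweighted least squares (via [stats::glm.fit()])
#' and never raises an error for a statistical failure: instead the
#' returned object carries a `failure_code` from the taxonomy
#' \describe{
#'   \item{none}{all coefficients finite;}
#'   \item{no_response_variation}{for binomial/Poisson-type families, the
#'     response is constant (e.g., a rare binary outcome absent from a
#'     bootstrap sample) and the MLE does not exist;}
#'   \item{rank_deficient_or_dropped_level}{one or more columns are
#'     collinear or all-zero (typically a factor level not drawn into the
#'     sample); those coefficients are `NA`, the rest are kept;}
#'   \item{nonconvergence}{IRLS hit the iteration cap, or a binomial-type
#'     fit shows coefficients beyond the separation threshold; all
#'     coefficients recorded as `NA` unless `keep_coefficients`;}
#'   \item{numerical_error}{the fitting routine itself raised.}
#' }
#'
#' @param X Numeric design matrix (intercept column included).
#' @param y Numeric response vector.
#' @param family Family spec, see [resolve_family()].
#' @param controls See [glm_controls()].
#' @param keep_coefficients Keep the (divergent) coefficients of a
#'   non-converged fit instead of replacing them by `NA`.
#' @return A list of class `glmcb_fitresult`: `coefficients` (named,
#'   possibly with `NA`s), `converged`, `failure_code`, `deviance`.
#' @export
fit_glm <- function(X, y, family = stats::gaussian(),
                    controls = glm_controls(), keep_coefficients = FALSE) {
  fam <- resolve_family(family)
  p <- ncol(X)
  nm <- colnames(X)
  if (nrow(X) < p)
    stop("design has fewer rows (", nrow(X), ") than coefficients (", p, ")")
  na_coef <- stats::setNames(rep(NA_real_, p), nm)

  if (is_discrete_family(fam) && length(unique(y)) < 2L) {
    return(structure(list(coefficients = na_coef, converged = FALSE,
                          failure_code = "no_response_variation",
                          deviance = NA_real_),
                     class = "glmcb_fitresult"))
  }

  fit <- tryCatch(
    suppressWarnings(
      stats::glm.fit(X, y, family = fam,
                     control = stats::glm.control(epsilon = controls$epsilon,
                                                  maxit = controls$maxit))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(coefficients = na_coef, converged = FALSE,
                          failure_code = "numerical_error",
                          deviance = NA_real_),
                     class = "glmcb_fitresult"))
  }

  # glm.fit returns the p coefficients in design-column order (NA where
  # aliased), so positional naming is safe even for unnamed columns
  cf <- stats::setNames(fit$coefficients, nm)
  code <- "none"
  converged <- isTRUE(fit$converged)
  separated <- fam$family %in% c("binomial", "quasibinomial") &&
    any(abs(cf) > controls$separation_threshold, na.rm = TRUE)
  if (!converged || separated) {
    code <- "nonconvergence"
    converged <- FALSE
    if (!keep_coefficients) cf[] <- NA_real_
  } else if (anyNA(cf)) {
    code <- "rank_deficient_or_dropped_level"
  }
  structure(list(coefficients = cf, converged = converged,
                 failure_code = code, deviance = fit$deviance),
            class = "glmcb_fitresult")
}

#' @export
print.glmcb_fitresult <- function(x, ...) {
  cat("GLM fit (", if (x$converged) "converged" else "NOT converged",
      "; failure_code = ", x$failure_code, ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Link and inverse-link functions
#'
#' The logit, log, and identity links with their inverses;
#' `inv_logit(logit(p)) == p` on (0, 1).
#'
#' @param p Probability in (0, 1).
#' @param x,mu Real number / positive mean.
#' @name links
#' @export
logit <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("logit() requires p in (0, 1)")
  log(p / (1 - p))
}

#' @rdname links
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' @rdname links
#' @export
log_link <- function(mu) {
  if (any(mu <= 0)) stop("log link requires mu > 0")
  log(mu)
}

#' @rdname links
#' @export
inv_log <- function(x) exp(x)

#' @rdname links
#' @export
identity_link <- function(mu) mu
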