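#' Clustered long-format data
#'
#' A `clustered_data` object is a long-format data frame (one row per
#' observation) together with the name of the column that identifies the
#' cluster each observation belongs to. The cluster is the unit of
#' resampling: all rows of a cluster travel together into every bootstrap
#' sample. Cluster labels are treated as opaque strings and are never
#' parsed as numbers.
#'
#' @param data A data frame in long format.
#' @param cluster Name of the cluster-identifier column.
#' @return An object of class `clustered_data`: the data frame with
#'   attributes `cluster` (column name) and `cluster_levels` (unique
#'   labels in order of first appearance).
#' @examples
#' d <- data.frame(id = rep(1:3, each = 2), y = rnorm(6), x = rnorm(6))
#' cd <- clustered_data(d, "id")
#' n_clusters(cd)
#' @export
clustered_data <- function(data, cluster) {
  if (!is.data.frame(data)) stop("`data` must be a data frame")
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("no rows in `data`")
  if (!is.character(cluster) || length(cluster) != 1L)
    stop("`cluster` must be a single column name")
  if (!cluster %in% names(data))
    stop("cluster column '", cluster, "' not found in data")
  ids <- data[[cluster]]
  bad <- which(is.na(ids) | (is.character(ids) & !nzchar(ids)))
  if (length(bad) > 0L)
    stop("missing cluster id in row(s): ", paste(utils::head(bad, 10L), collapse = ", "))
  data[[cluster]] <- as.character(ids)
  structure(data,
            cluster = cluster,
            cluster_levels = unique(data[[cluster]]),
            class = c("clustered_data", "data.frame"))
}

#' @rdname clustered_data
#' @param x A `clustered_data` object.
#' @export
n_clusters <- function(x) {
  length(attr(x, "cluster_levels"))
}

#' @rdname clustered_data
#' @export
cluster_ids <- function(x) {
  attr(x, "cluster_levels")
}

#' Row indices of each cluster, in order of first appearance
#'
#' @param x A `clustered_data` object.
#' @return Named list of integer row indices, one element per cluster.
#'   Within-cluster order is the row order of the parent data.
#' @keywords internal
cluster_rows <- function(x) {
  ids <- x[[attr(x, "cluster")]]
  lev <- attr(x, "cluster_levels")
  split(seq_along(ids), factor(ids, levels = lev))
}

#' Read clustered long-format data from a delimited text file
#'
#' Reads a CSV or TSV file with one row per observation and a cluster
#' identifier column. The delimiter is auto-detected from the header line
#' (tab wins over comma when both occur) unless given explicitly. Rows
#' with missing values in any column are dropped with a message, so that
#' downstream model frames never silently change the cluster structure.
#'
#' @param path Path to the file.
#' @param cluster Name of the cluster-identifier column.
#' @param sep Field delimiter; `NULL` (default) auto-detects.
#' @return A [clustered_data] object. Row order of the file is preserved.
#' @export
read_clustered_data <- function(path, cluster, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("no rows in file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA, comment.char = "")
  if (nrow(df) == 0L) stop("no rows in file: ", path)
  if (!cluster %in% names(df))
    stop("cluster column '", cluster, "' not found; columns are: ",
         paste(names(df), collapse = ", "))
  if (anyNA(df[[cluster]]))
    stop("missing cluster id in row(s): ",
         paste(utils::head(which(is.na(df[[cluster]])), 10L), collapse = ", "))
  complete <- stats::complete.cases(df)
  if (!all(complete)) {
    message("dropping ", sum(!complete), " row(s) with missing values")
    df <- df[complete, , drop = FALSE]
    rownames(df) <- NULL
  }
  clustered_data(df, cluster)
}

#' Write clustered data to a delimited text file
#'
#' Counterpart of [read_clustered_data()]. Numeric columns are written
#' with 17 significant digits so that a write/read cycle round-trips
#' double-precision values bit-exactly.
#'
#' @param x A `clustered_data` object or data frame.
#' @param path Output file path.
#' @param sep Field delimiter (default comma).
#' @return Invisibly, `path`.
#' @export
write_clustered_data <- function(x, path, sep = ",") {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Build a GLM design matrix from a model formula
#'
#' Expands a Wilkinson-notation formula (`+`, `:`, `*`, `- 1`) against a
#' dataset into the numeric design matrix and response vector used by the
#' fitting engine. Categorical predictors are expanded into dummy columns
#' with reference (treatment) coding; by default the baseline is the
#' lexicographically first level (the conventional `factor()` ordering),
#' overridable by passing factors with explicit levels. Random-effect or
#' nesting syntax (`|`, `/`) is rejected: the cluster bootstrap has no
#' random effects by design.
#'
#' Factor levels are frozen from the data supplied here; when the same
#' `terms`/`xlevels` are reapplied to a bootstrap sample, a level absent
#' from the sample still gets its (all-zero) column, which yields an `NA`
#' coefficient rather than a silently renumbered model.
#'
#' @param data A data frame or `clustered_data`.
#' @param formula A model formula, e.g. `pos ~ treat * time`.
#' @return A list of class `glmcb_design` with elements `X` (n x p numeric
#'   matrix, intercept column first), `y` (response vector), `terms`,
#'   `xlevels`, and `coef_names`.
#' @examples
#' d <- data.frame(pos = rnorm(8), treat = rep(0:1, each = 4), time = rep(0:3, 2))
#' des <- build_design(d, pos ~ treat * time)
#' colnames(des$X)  # (Intercept), treat, time, treat:time
#' @export
build_design <- function(data, formula) {
  formula <- stats::as.formula(formula)
  fstr <- paste(deparse(formula), collapse = " ")
  if (grepl("|", fstr, fixed = TRUE))
    stop("random-effect syntax '|' is not supported: the cluster bootstrap ",
         "handles within-cluster dependency by resampling, not random effects")
  tt <- stats::terms(formula, data = data)
  if (attr(tt, "response") != 1L)
    stop("formula must have a response on the left-hand side")
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0L)
    stop("variable(s) not found in data: ", paste(missing_vars, collapse = ", "))
  resp <- all.vars(formula[[2L]])
  if (any(resp %in% attr(tt, "term.labels")))
    stop("response '", resp[1L], "' also appears on the right-hand side")
  df <- as.data.frame(data)
  # freeze character predictors as factors with sorted (lexicographic) levels
  for (v in vars) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  }
  mf <- stats::model.frame(tt, df, na.action = stats::na.omit)
  X <- stats::model.matrix(tt, mf)
  y <- stats::model.response(mf)
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("factor response must have exactly 2 levels")
    y <- as.numeric(y != levels(y)[1L])
  }
  if (is.logical(y)) y <- as.numeric(y)
  structure(list(X = X, y = as.numeric(y), terms = tt,
                 xlevels = stats::.getXlevels(tt, mf),
                 coef_names = colnames(X)),
            class = "glmcb_design")
}

#' Reapply a frozen design to a (bootstrap) dataset
#'
#' Uses the `terms` and factor levels captured by [build_design()] on the
#' parent data, so that dropped factor levels produce all-zero columns
#' instead of a narrower design.
#'
#' @param design A `glmcb_design` from [build_design()].
#' @param data New data with the same variables.
#' @return A list with elements `X` and `y` as in [build_design()].
#' @keywords internal
apply_design <- function(design, data) {
  df <- as.data.frame(data)
  for (v in names(design$xlevels)) {
    df[[v]] <- factor(df[[v]], levels = design$xlevels[[v]])
  }
  mf <- stats::model.frame(design$terms, df, na.action = stats::na.pass,
                           xlev = design$xlevels)
  X <- stats::model.matrix(design$terms, mf)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.numeric(y != levels(y)[1L])
  list(X = X, y = as.numeric(y))
}
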