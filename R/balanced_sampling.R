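#' Balanced bootstrap cluster-index matrix
#'
#' Builds the N x B matrix of cluster positions that drives a balanced
#' cluster bootstrap. B copies of the integers 1..N are concatenated,
#' uniformly shuffled, and reshaped column-wise into an N x B matrix;
#' column b holds the cluster draws of bootstrap sample b. By
#' construction every cluster appears exactly B times across the whole
#' matrix (though any number of times, including zero, within a single
#' column), which removes simulation imbalance between clusters and, for
#' unequal cluster sizes, makes the average bootstrap-sample row count
#' equal to the parent row count.
#'
#' @param n_clusters Number of clusters N (>= 1).
#' @param B Number of bootstrap samples (>= 1).
#' @param seed Optional integer seed; when given, the matrix is fully
#'   reproducible from `(n_clusters, B, seed)`.
#' @return An integer N x B matrix with entries in `1:n_clusters`.
#' @examples
#' m <- build_balanced_indices(3, 4, seed = 1)
#' table(m)  # each of 1,2,3 appears exactly 4 times
#' @export
build_balanced_indices <- function(n_clusters, B, seed = NULL) {
  if (length(n_clusters) != 1L || is.na(n_clusters) || n_clusters < 1)
    stop("`n_clusters` must be a positive integer")
  if (length(B) != 1L || is.na(B) || B < 1)
    stop("`B` must be a positive integer")
  n_clusters <- as.integer(n_clusters)
  B <- as.integer(B)
  if (!is.null(seed)) set.seed(seed)
  v <- rep.int(seq_len(n_clusters), B)
  matrix(v[sample.int(length(v))], nrow = n_clusters, ncol = B)
}

#' Materialize one bootstrap sample from cluster indices
#'
#' Concatenates, in draw order, all rows of each drawn cluster. A cluster
#' drawn k times contributes k full copies of its rows; copies are
#' re-labelled with replicate-aware ids (`label#1`, `label#2`, ...) so the
#' GLM treats them as distinct clusters while provenance stays
#' recoverable. Within-cluster row order of the parent is preserved, so
#' any serial dependency structure inside a cluster is intact.
#'
#' @param dataset A [clustered_data] object.
#' @param indices Length-N vector of cluster positions (1..N), e.g. one
#'   column of [build_balanced_indices()].
#' @return A [clustered_data] object holding the bootstrap sample.
#' @export
materialize_sample <- function(dataset, indices) {
  if (!inherits(dataset, "clustered_data"))
    stop("`dataset` must be a clustered_data object")
  lev <- attr(dataset, "cluster_levels")
  N <- length(lev)
  indices <- as.integer(indices)
  if (anyNA(indices) || any(indices < 1L) || any(indices > N))
    stop("cluster index out of range 1..", N)
  rows <- cluster_rows(dataset)
  cl_col <- attr(dataset, "cluster")
  row_idx <- unlist(rows[indices], use.names = FALSE)
  out <- as.data.frame(dataset)[row_idx, , drop = FALSE]
  # replicate-aware relabelling: j-th occurrence of a cluster gets suffix #j
  occ <- stats::ave(indices, indices, FUN = seq_along)
  sizes <- lengths(rows)[indices]
  out[[cl_col]] <- rep(paste0(lev[indices], "#", occ), sizes)
  rownames(out) <- NULL
  clustered_data(out, cl_col)
}
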