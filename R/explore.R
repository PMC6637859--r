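#' Complete-linkage hierarchical clustering of rows
#'
#' Agglomerative clustering with complete linkage
#' (`D(A, B) = max` pairwise distance) on Euclidean distances between the
#' rows of `x` — for sample-level structure pass a sample x gene matrix.
#'
#' @param x numeric matrix; rows are the objects to cluster.
#' @return an [stats::hclust] object (merge sequence, non-decreasing merge
#'   heights, leaf order).
#' @export
hclust_complete <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 rows to cluster")
  if (any(!is.finite(x))) stop("validation error: non-finite values")
  stats::hclust(stats::dist(x, method = "euclidean"), method = "complete")
}

#' Cut a dendrogram into k groups
#'
#' Thin wrapper over [stats::cutree()] kept for a stable pipeline surface.
#'
#' @param h an [stats::hclust] object.
#' @param k number of clusters.
#' @return integer cluster memberships named by leaf label.
#' @export
cut_clusters <- function(h, k = 2) stats::cutree(h, k = k)

#' Principal component analysis of samples
#'
#' Centers each gene (column) and decomposes the centered matrix by SVD;
#' component signs are fixed so the largest-magnitude loading of each
#' component is positive. No per-gene variance scaling: intensities are
#' already on a common log2 scale.
#'
#' @param x sample x gene matrix.
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `loadings` (genes x components), `var_explained` (fractions summing
#'   to 1 over the kept components), `sdev`.
#' @export
pca_samples <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 samples")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  d2 <- sv$d^2
  if (sum(d2) < 1e-24) {
    warning("constant matrix: zero variance, all scores 0")
    ve <- rep(0, length(sv$d))
  } else {
    ve <- d2 / sum(d2)
  }
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  loadings <- sv$v
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- rownames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores, loadings = loadings,
                 var_explained = ve, sdev = sv$d / sqrt(max(1, nrow(x) - 1))),
            class = "pca_result")
}

#' Two-way heatmap ordering by independent hierarchical clustering
#'
#' Rows and columns are ordered independently by the leaf order of their
#' complete-linkage Euclidean dendrograms — the standard heatmap
#' convention for a two-way-clustered top-gene panel. Sides with fewer
#' than two elements keep identity order.
#'
#' @param x gene x sample matrix (typically the top-k DE genes).
#' @return list with `row_order`, `col_order` (integer indices) and
#'   `row_ids`, `col_ids` (the corresponding labels, when present).
#' @export
heatmap_order <- function(x) {
  x <- as.matrix(x)
  row_order <- if (nrow(x) >= 2) hclust_complete(x)$order else seq_len(nrow(x))
  col_order <- if (ncol(x) >= 2) hclust_complete(t(x))$order else
    seq_len(ncol(x))
  list(row_order = row_order, col_order = col_order,
       row_ids = rownames(x)[row_order], col_ids = colnames(x)[col_order])
}
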