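#' Hypergeometric overrepresentation analysis of a gene list
#'
#' For each term with member set of size `K` (after intersection with the
#' universe of size `N`) and a DE list of size `n` overlapping it in `k`
#' genes, the upper-tail hypergeometric probability `P(X >= k)` is
#' computed; Benjamini-Hochberg adjustment is applied within each
#' namespace separately (mirroring per-namespace reporting); terms outside
#' the size bounds are excluded. Results are sorted by adjusted p, then
#' term id.
#'
#' @param de_genes character vector of selected genes (subset of
#'   `universe`).
#' @param universe character vector: all genes eligible for selection
#'   (typically every gene surviving preprocessing).
#' @param collection a [gene_set_collection()].
#' @param min_size,max_size bounds on the in-universe term size.
#' @return data.frame with `term_id`, `term_name`, `namespace`, `overlap`,
#'   `set_size`, `de_size`, `universe_size`, `p_value`, `p_fdr`.
#' @export
ora <- function(de_genes, universe, collection, min_size = 2,
                max_size = 2000) {
  universe <- unique(universe)
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe))
    stop("de_genes must be a subset of the universe")
  empty <- data.frame(term_id = character(), term_name = character(),
                      namespace = character(), overlap = integer(),
                      set_size = integer(), de_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      p_fdr = numeric(), stringsAsFactors = FALSE)
  if (length(de_genes) == 0) {
    warning("empty DE list: returning no ORA results")
    return(empty)
  }
  N <- length(universe)
  n <- length(de_genes)
  rows <- lapply(collection, function(tm) {
    members <- intersect(tm$genes, universe)
    K <- length(members)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(members, de_genes))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm$term_id, term_name = tm$term_name,
               namespace = tm$namespace, overlap = k, set_size = K,
               de_size = n, universe_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  for (ns in unique(out$namespace)) {
    idx <- out$namespace == ns
    out$p_fdr[idx] <- bh_adjust(out$p_value[idx])
  }
  out <- out[order(out$p_fdr, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Random-forest Gini importance of genes for group classification
#'
#' Trains a random-forest classifier of samples by group label on gene
#' expression features (bootstrap resampling of samples, `sqrt(p)` features
#' per split) and returns each gene's mean decrease in Gini impurity
#' across trees. Deterministic given the seed.
#'
#' @param collapsed a collapsed-state [intensity_table()].
#' @param design design data.frame (`sample_id`, `group`).
#' @param n_trees number of trees.
#' @param seed integer RNG seed.
#' @return data.frame of class `gini_importance` with `gene`, `importance`;
#'   attributes `n_trees`, `mtry`, `seed`, `labels`.
#' @export
rf_importance <- function(collapsed, design, n_trees = 1000, seed = 1L) {
  stopifnot(inherits(collapsed, "intensity_table"))
  if (collapsed$state != "collapsed")
    stop("state error: rf_importance expects a collapsed table")
  design <- validate_design(design, collapsed)
  x <- t(collapsed$values[, design$sample_id, drop = FALSE])
  y <- factor(design$group, levels = attr(design, "group_levels"))
  if (nlevels(y) > nrow(x)) stop("more groups than samples")
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                    importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  out <- data.frame(gene = colnames(x), importance = as.vector(imp),
                    stringsAsFactors = FALSE)
  attr(out, "n_trees") <- n_trees
  attr(out, "mtry") <- fit$mtry
  attr(out, "seed") <- as.integer(seed)
  attr(out, "labels") <- as.character(y)
  class(out) <- c("gini_importance", "data.frame")
  out
}

#' Aggregate gene importance scores over gene-set terms
#'
#' A term's score is the arithmetic mean importance of its annotated genes
#' present in the importance table; the mapped-gene count is recorded.
#' Terms mapping no scored gene are excluded (with a message). Invariant to
#' member ordering and duplication.
#'
#' @param importance a `gini_importance` data.frame (see
#'   [rf_importance()]).
#' @param collection a [gene_set_collection()].
#' @return data.frame with `term_id`, `term_name`, `namespace`, `score`,
#'   `n_mapped`.
#' @export
aggregate_terms <- function(importance, collection) {
  scores <- stats::setNames(importance$importance, importance$gene)
  rows <- lapply(collection, function(tm) {
    mapped <- unique(tm$genes[tm$genes %in% names(scores)])
    if (length(mapped) == 0) return(NULL)
    data.frame(term_id = tm$term_id, term_name = tm$term_name,
               namespace = tm$namespace, score = mean(scores[mapped]),
               n_mapped = length(mapped), stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " term(s) with no mapped genes excluded")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation p-value for a term's aggregated score
#'
#' Empirical p-value of the observed mean importance against `n_perm`
#' same-size gene sets sampled without replacement from all scored genes:
#' `p = (1 + #{perm >= observed}) / (n_perm + 1)`. Comparisons use a tiny
#' relative tolerance so exact ties (e.g. the term equal to the whole
#' universe) are always counted.
#'
#' @param observed the term's observed mean importance.
#' @param size the term's mapped-gene count (>= 1).
#' @param importance a `gini_importance` data.frame.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @return the permutation p-value.
#' @export
permutation_p <- function(observed, size, importance, n_perm = 1000,
                          seed = 1L) {
  scores <- importance$importance
  if (size < 1) stop("term size must be >= 1")
  if (size > length(scores)) stop("term size exceeds the scored universe")
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm),
                 function(i) mean(scores[sample.int(length(scores), size)]),
                 numeric(1))
  tol <- 1e-12 * max(1, abs(observed))
  (1 + sum(perm >= observed - tol)) / (n_perm + 1)
}

#' Add permutation p-values to a term-score table
#'
#' Runs [permutation_p()] for every term, with per-term seeds derived
#' deterministically from `seed`.
#'
#' @param terms term-score data.frame from [aggregate_terms()].
#' @param importance a `gini_importance` data.frame.
#' @param n_perm permutations per term.
#' @param seed base seed.
#' @return `terms` with an added `p_value` column.
#' @export
add_permutation_p <- function(terms, importance, n_perm = 1000, seed = 1L) {
  terms$p_value <- vapply(seq_len(nrow(terms)), function(i) {
    permutation_p(terms$score[i], terms$n_mapped[i], importance,
                  n_perm = n_perm, seed = as.integer(seed) + i)
  }, numeric(1))
  terms
}

#' Select top-importance genes and significant biological-process terms
#'
#' Genes: the `n_top` highest-importance genes (ties broken by gene id).
#' Terms: namespace BP with permutation `p_value < p_thresh` (strict) and
#' mapped-gene count `>= min_count`. Defaults follow the study's filters:
#' top 1,000 genes, term p < 0.01, count >= 10. Both selections feed the
#' hot-spot detector.
#'
#' @param terms term-score data.frame with a `p_value` column.
#' @param importance a `gini_importance` data.frame.
#' @param n_top number of genes to keep.
#' @param p_thresh term p-value cutoff (strict).
#' @param min_count minimum mapped-gene count.
#' @return list with `genes` (character) and `terms` (the selected rows).
#' @export
filter_and_select <- function(terms, importance, n_top = 1000,
                              p_thresh = 0.01, min_count = 10) {
  n <- nrow(importance)
  if (n < n_top) {
    warning("only ", n, " scored genes available; selecting all")
    n_top <- n
  }
  o <- order(-importance$importance, importance$gene)
  genes <- importance$gene[o][seq_len(n_top)]
  keep <- terms$namespace == "BP" & terms$p_value < p_thresh &
    terms$n_mapped >= min_count
  list(genes = genes, terms = terms[keep, , drop = FALSE])
}
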