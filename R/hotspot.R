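#' Weighted binary gene-by-term incidence matrix
#'
#' @param B binary matrix (genes in rows, terms in columns) with dimnames.
#' @param weights non-negative per-gene weights (e.g. Gini importance),
#'   named by gene or in row order.
#' @return object of class `incidence_matrix` with elements `B` (integer
#'   0/1 matrix) and `weights`.
#' @export
incidence_matrix <- function(B, weights = rep(1, nrow(B))) {
  B <- as.matrix(B)
  if (nrow(B) == 0 || ncol(B) == 0) stop("rows and columns must be non-empty")
  if (!all(B %in% c(0, 1))) stop("incidence matrix must be binary")
  if (is.null(rownames(B))) rownames(B) <- sprintf("g%03d", seq_len(nrow(B)))
  if (is.null(colnames(B))) colnames(B) <- sprintf("t%03d", seq_len(ncol(B)))
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), rownames(B)))
      stop("weight names must match row names")
    weights <- weights[rownames(B)]
  } else if (length(weights) != nrow(B)) {
    stop("need one weight per row")
  }
  if (any(weights < 0)) stop("weights must be >= 0")
  mode(B) <- "integer"
  structure(list(B = B, weights = stats::setNames(as.numeric(weights),
                                                  rownames(B))),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("incidence_matrix: %d genes x %d terms, density %.3f\n",
              nrow(x$B), ncol(x$B), mean(x$B)))
  invisible(x)
}

#' Hot-spot search parameters
#'
#' @param gamma penalty weight on zeros inside the bicluster (>= 0). At
#'   `gamma = 0` absent links cost nothing and the optimum degenerates to
#'   all rows/columns containing any positively-weighted link.
#' @param seeding `"each-column"` restarts the search from every column;
#'   `"densest-column"` seeds only from the column with the largest
#'   weighted membership.
#' @param max_iter iteration cap per seed.
#' @return list of class `hotspot_params`.
#' @export
hotspot_params <- function(gamma = 1, seeding = c("each-column",
                                                  "densest-column"),
                           max_iter = 100) {
  if (gamma < 0) stop("gamma must be >= 0")
  structure(list(gamma = gamma, seeding = match.arg(seeding),
                 max_iter = max_iter), class = "hotspot_params")
}

#' Score a bicluster
#'
#' The weighted-density objective
#' `S(G, T) = sum_{g in G} sum_{t in T} w_g (B_gt - gamma (1 - B_gt))`:
#' each present link contributes the gene's weight, each absent link inside
#' the bicluster costs `gamma` times it. The empty selection scores 0.
#'
#' @param M an [incidence_matrix()].
#' @param genes,terms character vectors of selected row/column ids.
#' @param gamma zero-penalty weight.
#' @return the score.
#' @export
score_bicluster <- function(M, genes, terms, gamma = 1) {
  stopifnot(inherits(M, "incidence_matrix"))
  if (length(genes) == 0 || length(terms) == 0) return(0)
  if (!all(genes %in% rownames(M$B)))
    stop("validation error: unknown gene id(s)")
  if (!all(terms %in% colnames(M$B)))
    stop("validation error: unknown term id(s)")
  sub <- M$B[genes, terms, drop = FALSE]
  k <- rowSums(sub)
  sum(M$weights[genes] * (k - gamma * (length(terms) - k)))
}

# per-row gains given a fixed column set: w_g * (k_g - gamma (|T| - k_g))
row_gains <- function(M, terms, gamma) {
  k <- rowSums(M$B[, terms, drop = FALSE])
  M$weights * (k - gamma * (length(terms) - k))
}

# per-column gains given a fixed row set: sum_g w_g (B - gamma (1 - B))
col_gains <- function(M, genes, gamma) {
  w <- M$weights[genes]
  sub <- M$B[genes, , drop = FALSE]
  as.vector(crossprod(sub, w) - gamma * crossprod(1L - sub, w))
}

#' Detect the enrichment hot spot by alternating bivariate maximization
#'
#' From each seed (a single column and its annotated genes) the search
#' alternates two exact half-steps — fix the term set and keep exactly the
#' genes with positive score contribution, then fix the gene set and keep
#' exactly the terms with positive contribution. Because the objective is
#' separable, each half-step is the exact maximizer over all subsets of its
#' side, so the score is non-decreasing and the search stops at a fixed
#' point (or `max_iter`). The best-scoring bicluster over all seeds is
#' returned; ties are broken by larger area `|G| * |T|`, then
#' lexicographically smallest sorted gene ids.
#'
#' @param M an [incidence_matrix()].
#' @param params a [hotspot_params()].
#' @return list of class `bicluster`: `genes`, `terms`, `score`,
#'   `iterations`, `converged`.
#' @export
alternate_maximize <- function(M, params = hotspot_params()) {
  stopifnot(inherits(M, "incidence_matrix"))
  gamma <- params$gamma
  all_terms <- colnames(M$B)
  # restarts: single columns plus one all-columns seed; the latter lets the
  # search reach the union of disconnected components at gamma = 0, where
  # single-column seeds cannot cross zero-gain boundaries
  seeds <- if (params$seeding == "each-column") {
    c(as.list(all_terms), list(all_terms))
  } else {
    list(all_terms[which.max(as.vector(crossprod(M$B, M$weights)))])
  }
  empty <- structure(list(genes = character(), terms = character(),
                          score = 0, iterations = 0L, converged = TRUE),
                     class = "bicluster")
  if (sum(M$B) == 0) {
    warning("all-zero incidence matrix: empty bicluster")
    return(empty)
  }
  best <- empty
  for (seed in seeds) {
    terms <- seed
    genes <- character()
    score <- -Inf
    converged <- FALSE
    iter <- 0L
    while (iter < params$max_iter) {
      iter <- iter + 1L
      rg <- row_gains(M, terms, gamma)
      new_genes <- names(rg)[rg > 0]
      if (length(new_genes) == 0) { genes <- character(); terms <- character(); score <- 0; converged <- TRUE; break }
      cg <- col_gains(M, new_genes, gamma)
      new_terms <- colnames(M$B)[cg > 0]
      if (length(new_terms) == 0) { genes <- character(); terms <- character(); score <- 0; converged <- TRUE; break }
      new_score <- sum(cg[cg > 0])
      if (new_score < score - 1e-9)
        stop("internal error: objective decreased")  # monotonicity guard
      if (setequal(new_genes, genes) && setequal(new_terms, terms)) {
        converged <- TRUE
        break
      }
      genes <- new_genes
      terms <- new_terms
      score <- new_score
    }
    cand <- structure(list(genes = sort(genes), terms = sort(terms),
                           score = if (length(genes)) score else 0,
                           iterations = iter, converged = converged),
                      class = "bicluster")
    if (better_bicluster(cand, best)) best <- cand
  }
  best
}

# tie-break comparator: score, then area, then lexicographic gene ids
better_bicluster <- function(a, b) {
  if (a$score > b$score + 1e-12) return(TRUE)
  if (a$score < b$score - 1e-12) return(FALSE)
  area_a <- length(a$genes) * length(a$terms)
  area_b <- length(b$genes) * length(b$terms)
  if (area_a != area_b) return(area_a > area_b)
  key_a <- paste(a$genes, collapse = "|")
  key_b <- paste(b$genes, collapse = "|")
  key_a < key_b
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("bicluster: %d genes x %d terms, score %.4g (%d iterations%s)\n",
              length(x$genes), length(x$terms), x$score, x$iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Exhaustive-enumeration hot-spot oracle
#'
#' Enumerates every non-empty (gene subset, term subset) pair — plus the
#' empty selection at score 0 — and returns the exact global maximizer of
#' [score_bicluster()], with the same tie-break as [alternate_maximize()].
#' Only feasible for `nrow + ncol <= 22`.
#'
#' @param M an [incidence_matrix()].
#' @param gamma zero-penalty weight.
#' @return a `bicluster` (see [alternate_maximize()]).
#' @export
brute_force_hotspot <- function(M, gamma = 1) {
  stopifnot(inherits(M, "incidence_matrix"))
  n <- nrow(M$B); m <- ncol(M$B)
  if (n + m > 22) stop("size error: instance too large for enumeration")
  genes <- rownames(M$B); terms <- colnames(M$B)
  # contribution of gene g to score under term set T:
  # w_g * (k_g(T) - gamma (|T| - k_g(T)))
  tmasks <- seq_len(2^m - 1)
  gmasks <- seq_len(2^n - 1)
  tm_member <- vapply(seq_len(m), function(t) bitwAnd(tmasks, 2^(t - 1)) > 0,
                      logical(length(tmasks)))
  if (!is.matrix(tm_member)) tm_member <- matrix(tm_member, nrow = 1)
  best <- structure(list(genes = character(), terms = character(),
                         score = 0, iterations = 0L, converged = TRUE),
                    class = "bicluster")
  signed <- M$weights * (M$B - gamma * (1 - M$B))  # gene x term gain parts
  gm_member <- vapply(seq_len(n), function(g) bitwAnd(gmasks, 2^(g - 1)) > 0,
                      logical(length(gmasks)))
  if (!is.matrix(gm_member)) gm_member <- matrix(gm_member, nrow = 1)
  for (ti in seq_along(tmasks)) {
    tsel <- which(tm_member[ti, ])
    gain <- rowSums(signed[, tsel, drop = FALSE])
    scores <- as.vector(gm_member %*% gain)
    for (gi in which(scores >= best$score - 1e-12)) {
      cand <- structure(list(genes = sort(genes[gm_member[gi, ]]),
                             terms = sort(terms[tsel]), score = scores[gi],
                             iterations = 0L, converged = TRUE),
                        class = "bicluster")
      if (better_bicluster(cand, best)) best <- cand
    }
  }
  best
}

#' Edge-list report of a hot spot for circular layouts
#'
#' Lists every present gene-term link inside the bicluster with the gene's
#' weight, plus a summary line of the form `"N genes linked with M terms"`.
#'
#' @param bicluster a `bicluster`.
#' @param M the [incidence_matrix()] it was found in.
#' @return list with `edges` (data.frame `gene`, `term`, `weight`) and
#'   `summary` (character).
#' @export
report_hotspot <- function(bicluster, M) {
  stopifnot(inherits(bicluster, "bicluster"), inherits(M, "incidence_matrix"))
  if (length(bicluster$genes) == 0) {
    return(list(edges = data.frame(gene = character(), term = character(),
                                   weight = numeric(),
                                   stringsAsFactors = FALSE),
                summary = "0 genes linked with 0 terms"))
  }
  sub <- M$B[bicluster$genes, bicluster$terms, drop = FALSE]
  idx <- which(sub == 1L, arr.ind = TRUE)
  edges <- data.frame(gene = rownames(sub)[idx[, 1]],
                      term = colnames(sub)[idx[, 2]],
                      weight = M$weights[rownames(sub)[idx[, 1]]],
                      stringsAsFactors = FALSE, row.names = NULL)
  edges <- edges[order(edges$gene, edges$term), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges,
       summary = sprintf("%d genes linked with %d terms",
                         length(bicluster$genes), length(bicluster$terms)))
}
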