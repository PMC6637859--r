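#' Fit per-gene group-means linear models
#'
#' Ordinary least squares under a group-means (cell-means) parameterization:
#' the coefficient of each group is its sample mean, the residual variance
#' is `RSS / d` with `d = n_samples - n_groups` (identical for all genes;
#' `d = 3` for the 3-group, n = 2 design).
#'
#' @param collapsed a collapsed-state [intensity_table()] (genes x samples,
#'   log2 scale).
#' @param design design data.frame (`sample_id`, `group`), see
#'   [validate_design()].
#' @return list of class `de_fit`: `coefficients` (genes x groups matrix of
#'   group means), `s2` (residual variances), `df_residual`, `n_per_group`,
#'   `groups`, `genes`.
#' @export
fit_models <- function(collapsed, design) {
  stopifnot(inherits(collapsed, "intensity_table"))
  if (collapsed$state != "collapsed")
    stop("state error: fit_models expects a collapsed table")
  design <- validate_design(design, collapsed)
  x <- collapsed$values[, design$sample_id, drop = FALSE]
  levels <- attr(design, "group_levels")
  grp <- factor(design$group, levels = levels)
  n <- ncol(x)
  k <- nlevels(grp)
  d <- n - k
  if (d == 0)
    stop("zero residual degrees of freedom (one sample per group ",
         "everywhere); variance moderation cannot rescue zero df")
  means <- vapply(levels, function(g)
    rowMeans(x[, grp == g, drop = FALSE]), numeric(nrow(x)))
  if (!is.matrix(means))
    means <- matrix(means, nrow = 1, dimnames = list(NULL, levels))
  fitted <- means[, as.integer(grp), drop = FALSE]
  rss <- rowSums((x - fitted)^2)
  structure(list(coefficients = means, s2 = rss / d, df_residual = d,
                 n_per_group = as.vector(table(grp)[levels]),
                 groups = levels, genes = collapsed$probe_id),
            class = "de_fit")
}

# invert the trigamma function: find x > 0 with trigamma(x) = target.
# Newton iteration on the reciprocal scale (monotone, globally convergent),
# as is standard for this inversion; tolerance on the reproduced target.
trigamma_inverse <- function(target, tol = 1e-10, max_iter = 100) {
  if (target <= 0) return(Inf)
  x <- 0.5 + 1 / target
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / target) / psigamma(x, 2L)
    x <- x + dif
    if (abs(tri - target) < tol * target && abs(dif) < 1e-8 * (x + 1))
      break
  }
  x
}

#' Estimate the variance prior by moment matching on log variances
#'
#' Under the scaled-inverse-chi-squared hierarchical model the log residual
#' variances satisfy
#' `e_g = log(s2_g) - digamma(d/2) + log(d/2)` with
#' `var(e) = trigamma(d/2) + trigamma(d0/2)` and
#' `mean(e) = log(s0^2) - digamma(d0/2) + log(d0/2)`.
#' `d0` is obtained by inverting the trigamma (Newton, tolerance 1e-10);
#' when the excess variance is non-positive, `d0 = Inf` and
#' `s0^2 = exp(mean(e))`.
#'
#' @param fit a `de_fit` from [fit_models()] with >= 100 genes with
#'   positive residual variance.
#' @return list with `d0` (prior df, possibly `Inf`) and `s02` (prior
#'   variance).
#' @export
estimate_prior <- function(fit) {
  stopifnot(inherits(fit, "de_fit"))
  s2 <- fit$s2[fit$s2 > 0]
  if (length(s2) == 0) stop("degenerate fit: all residual variances are 0")
  if (length(s2) < 100)
    stop("need >= 100 genes with positive residual variance")
  d <- fit$df_residual
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  excess <- stats::var(e) - trigamma(d / 2)
  if (excess <= 0) {
    return(list(d0 = Inf, s02 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Default pairwise contrasts over ordered group levels
#'
#' Builds the later-vs-earlier pairwise contrasts (for levels C, S, R:
#' `S_vs_C`, `R_vs_C`, `R_vs_S`), each a weight vector over group means
#' summing to zero.
#'
#' @param groups ordered group labels.
#' @return named list of weight vectors.
#' @export
default_contrasts <- function(groups) {
  out <- list()
  for (j in seq_along(groups)) {
    for (i in seq_len(j - 1L)) {
      w <- stats::setNames(numeric(length(groups)), groups)
      w[groups[j]] <- 1
      w[groups[i]] <- -1
      out[[paste0(groups[j], "_vs_", groups[i])]] <- w
    }
  }
  out
}

#' Moderated t-statistics and p-values per contrast
#'
#' Shrinks each gene's residual variance toward the prior,
#' `s2_post = (d0 s0^2 + d s2_g) / (d0 + d)`, and tests each contrast `w`
#' with `t = (w' beta) / sqrt(s2_post * sum(w_j^2 / n_j))`, two-sided
#' p-values from the t distribution on `d0 + d` df (standard normal when
#' `d0 = Inf`). Benjamini-Hochberg adjustment is applied within each
#' contrast separately. Genes with `s2_post = 0` get `p = 0` and are
#' flagged in the `degenerate` column.
#'
#' @param fit a `de_fit`.
#' @param prior list with `d0`, `s02` (see [estimate_prior()]).
#' @param contrasts named list of weight vectors over group means; default
#'   all pairwise contrasts.
#' @return data.frame of class `moderated_stats` with columns `gene`,
#'   `contrast`, `logFC`, `t`, `p_value`, `p_fdr`, `degenerate`; attributes
#'   `d0`, `s02`, `df_total`.
#' @export
moderate_and_test <- function(fit, prior, contrasts = NULL) {
  stopifnot(inherits(fit, "de_fit"))
  if (is.null(contrasts)) contrasts <- default_contrasts(fit$groups)
  d <- fit$df_residual
  d0 <- prior$d0
  s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(fit$s2)) else
    (d0 * s02 + d * fit$s2) / (d0 + d)
  df_total <- d0 + d
  res <- lapply(names(contrasts), function(nm) {
    w <- contrasts[[nm]][fit$groups]
    if (abs(sum(w)) > 1e-12) stop("contrast weights must sum to 0")
    v <- sum(w^2 / fit$n_per_group)
    lfc <- as.vector(fit$coefficients %*% w)
    degen <- s2_post == 0
    tt <- ifelse(degen, sign(lfc) * Inf, lfc / sqrt(s2_post * v))
    p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tt)) else
      2 * stats::pt(-abs(tt), df = df_total)
    p[degen] <- 0
    data.frame(gene = fit$genes, contrast = nm, logFC = lfc, t = tt,
               p_value = p, p_fdr = bh_adjust(p), degenerate = degen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "df_total") <- df_total
  class(out) <- c("moderated_stats", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Validates the input and applies the BH step-up rule
#' (`adj_(i) = min_{j >= i} m p_(j) / j`, capped at 1, mapped back to
#' input order).
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return vector of adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("validation error: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes at the pipeline cutoffs
#'
#' A gene is DE-up in a contrast iff `p_fdr < p_thresh` and
#' `logFC > lfc_thresh`; DE-down iff `p_fdr < p_thresh` and
#' `logFC < -lfc_thresh`. Both inequalities are strict. Defaults are the
#' study cutoffs: adjusted p < 0.05, |log2 fold change| > 2 (fold change
#' > 4).
#'
#' @param stats a `moderated_stats` data.frame.
#' @param p_thresh adjusted-p cutoff.
#' @param lfc_thresh absolute log2-fold-change cutoff.
#' @return list of class `de_calls`: per contrast a list with `up` and
#'   `down` gene vectors, plus a `summary` data.frame of counts.
#' @export
call_de <- function(stats, p_thresh = 0.05, lfc_thresh = 2) {
  if (lfc_thresh < 0 || p_thresh <= 0)
    stop("validation error: thresholds must be positive")
  contrasts <- unique(stats$contrast)
  calls <- lapply(contrasts, function(nm) {
    s <- stats[stats$contrast == nm, ]
    list(up = sort(s$gene[s$p_fdr < p_thresh & s$logFC > lfc_thresh]),
         down = sort(s$gene[s$p_fdr < p_thresh & s$logFC < -lfc_thresh]))
  })
  names(calls) <- contrasts
  summary <- data.frame(
    contrast = contrasts,
    n_up = vapply(calls, function(cc) length(cc$up), integer(1)),
    n_down = vapply(calls, function(cc) length(cc$down), integer(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(c(calls, list(summary = summary)), class = "de_calls")
}

#' Volcano-plot table for one contrast
#'
#' Rows sorted by gene id; `neg_log10_p` is `-log10` of the raw moderated
#' p-value; the `de` flag matches [call_de()] at the same thresholds.
#'
#' @param stats a `moderated_stats` data.frame.
#' @param contrast contrast name.
#' @param p_thresh,lfc_thresh cutoffs for the DE flag.
#' @return data.frame with `gene`, `logFC`, `neg_log10_p`, `de`.
#' @export
volcano_table <- function(stats, contrast, p_thresh = 0.05,
                          lfc_thresh = 2) {
  s <- stats[stats$contrast == contrast, ]
  if (nrow(s) == 0) stop("unknown contrast: ", contrast)
  s <- s[order(s$gene), ]
  data.frame(gene = s$gene, logFC = s$logFC,
             neg_log10_p = -log10(s$p_value),
             de = s$p_fdr < p_thresh & abs(s$logFC) > lfc_thresh,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Top-k genes by adjusted p over the union of contrasts
#'
#' Each gene is ranked by its smallest adjusted p-value across contrasts;
#' ties are broken by the absolute log2 fold change (descending, taken at
#' the minimizing contrast), then by gene id.
#'
#' @param stats a `moderated_stats` data.frame.
#' @param k number of genes to return.
#' @return character vector of gene ids.
#' @export
top_k_table <- function(stats, k = 50) {
  split_g <- split(seq_len(nrow(stats)), stats$gene)
  best <- vapply(split_g, function(idx) {
    i <- idx[order(stats$p_fdr[idx], -abs(stats$logFC[idx]))[1L]]
    c(stats$p_fdr[i], abs(stats$logFC[i]))
  }, numeric(2))
  genes <- names(split_g)
  o <- order(best[1, ], -best[2, ], genes)
  if (k > length(genes)) {
    warning("k exceeds gene count; returning all ", length(genes), " genes")
    k <- length(genes)
  }
  genes[o][seq_len(k)]
}
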