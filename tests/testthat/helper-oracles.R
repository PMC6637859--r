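# Independent oracles used across test files.

# Benjamini-Hochberg from its definition: adj_(i) = min_{j >= i} m p_(j) / j,
# capped at 1, mapped back to input order. Suffix minimum via reverse cummin.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# literal O(m^2) version of the same definition, for small vectors
bh_stepup_literal <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact hypergeometric upper tail by exhaustive enumeration of all n-subsets
# of a universe of size N with K marked elements: P(overlap >= k)
hyper_upper_enum <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  mean(overlap >= k)
}

# quadrature oracle for E[S | X = x] under S ~ Exp(alpha), B ~ N(mu, sigma^2)
normexp_signal_quadrature <- function(x, mu, sigma, alpha) {
  joint <- function(s) exp(-s / alpha) * stats::dnorm(x - s, mu, sigma)
  # the posterior mass lives within a few sigma of x - mu; restrict the
  # integration window so the adaptive rule cannot miss a narrow spike
  lo <- max(0, x - mu - 15 * sigma)
  hi <- max(x - mu, 0) + 15 * sigma
  num <- stats::integrate(function(s) s * joint(s), lo, hi,
                          rel.tol = 1e-12)$value
  den <- stats::integrate(joint, lo, hi, rel.tol = 1e-12)$value
  num / den
}

# collapsed intensity table straight from a matrix (log2 scale)
collapsed_table <- function(x) {
  intensity_table(x, rownames(x), rownames(x), rep(FALSE, nrow(x)),
                  state = "collapsed", log2 = TRUE)
}

# design for k groups x n samples matching synthgen's sample naming
make_design <- function(groups = c("C", "S", "R"), n_per_group = 2) {
  data.frame(sample_id = paste(rep(groups, each = n_per_group),
                               seq_len(n_per_group), sep = "_"),
             group = rep(groups, each = n_per_group),
             stringsAsFactors = FALSE)
}

# did complete-linkage clustering isolate the two R samples?
r_samples_isolated <- function(collapsed) {
  ct <- cut_clusters(hclust_complete(t(collapsed$values)), k = 2)
  r <- grepl("^R_", names(ct))
  length(unique(ct[r])) == 1 && length(unique(ct[!r])) == 1 &&
    ct[r][1] != ct[!r][1]
}
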