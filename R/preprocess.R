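#' Estimate normal+exponential background parameters for one array
#'
#' Background mean `mu` and SD `sigma` come from the control probes when at
#' least five are available (their mean and SD), otherwise from the lowest
#' decile of intensities; the exponential signal mean `alpha` is
#' `max(mean(x) - mu, floor)`.
#'
#' @param x positive raw intensities of one sample column (>= 10 values).
#' @param control_mask optional logical vector flagging control probes.
#' @param sigma_floor lower bound for `sigma` (and the `alpha` floor).
#' @return list with `mu`, `sigma`, `alpha` (class `normexp_params`).
#' @export
estimate_normexp <- function(x, control_mask = NULL, sigma_floor = 1e-4) {
  if (length(x) < 10) stop("estimation error: need >= 10 values")
  if (stats::sd(x) == 0) stop("estimation error: all-constant input")
  use_controls <- !is.null(control_mask) && sum(control_mask) >= 5
  if (use_controls) {
    ctrl <- x[control_mask]
    mu <- mean(ctrl)
    sigma <- max(stats::sd(ctrl), sigma_floor)
  } else {
    low <- x[x <= stats::quantile(x, 0.1)]
    mu <- mean(low)
    sigma <- max(stats::sd(low), sigma_floor)
  }
  alpha <- max(mean(x) - mu, sigma_floor)
  structure(list(mu = mu, sigma = sigma, alpha = alpha),
            class = "normexp_params")
}

# conditional expectation E[S | X = x] under X = S + B, S ~ Exp(alpha),
# B ~ N(mu, sigma^2); computed on the log scale for tail stability
normexp_signal <- function(x, mu, sigma, alpha) {
  m <- x - mu - sigma^2 / alpha
  z <- m / sigma
  out <- m + sigma * exp(stats::dnorm(z, log = TRUE) -
                           stats::pnorm(z, log.p = TRUE))
  pmax(out, 1e-10)  # strictly positive; guards roundoff at extreme tails
}

#' Background-correct a raw intensity table
#'
#' Each value `x` is replaced by the posterior mean `E[S | X = x]` of the
#' true signal under the normal+exponential convolution model
#' `X = S + B`, `S >= 0` exponential, `B ~ N(mu, sigma^2)`:
#' with `m = x - mu - sigma^2/alpha`,
#' `E[S|X=x] = m + sigma * phi(m/sigma) / Phi(m/sigma)`.
#' Outputs are strictly positive. A simple `subtract` alternative
#' (`max(x - mu, floor)`) is available behind `method`.
#'
#' @param table raw-state [intensity_table()].
#' @param params optional list of [estimate_normexp()] results, one per
#'   sample; estimated from each column (using the control probes) when
#'   missing.
#' @param method `"normexp"` (default) or `"subtract"`.
#' @return the corrected table, state `background_corrected`.
#' @export
background_correct <- function(table, params = NULL,
                               method = c("normexp", "subtract")) {
  stopifnot(inherits(table, "intensity_table"))
  method <- match.arg(method)
  if (table$state != "raw")
    stop("state error: background correction expects a raw table, got '",
         table$state, "'")
  x <- table$values
  if (is.null(params)) {
    params <- lapply(seq_len(ncol(x)), function(j)
      estimate_normexp(x[, j], table$is_control))
  }
  if (inherits(params, "normexp_params")) params <- rep(list(params), ncol(x))
  if (length(params) != ncol(x))
    stop("need one parameter set per sample column")
  out <- x
  for (j in seq_len(ncol(x))) {
    p <- params[[j]]
    out[, j] <- if (method == "normexp") {
      normexp_signal(x[, j], p$mu, p$sigma, p$alpha)
    } else {
      pmax(x[, j] - p$mu, 0.5)
    }
  }
  intensity_table(out, table$probe_id, table$gene_symbol, table$is_control,
                  state = "background_corrected", log2 = FALSE)
}

#' Log2-transform a table
#'
#' Applies `log2(x + offset)`; the +1 offset keeps values below 1 from
#' exploding to large negatives.
#'
#' @param table an [intensity_table()].
#' @param offset additive offset before the log.
#' @return the transformed table (same state, `log2 = TRUE`).
#' @export
log2_transform <- function(table, offset = 1) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$log2) stop("table is already on the log2 scale")
  intensity_table(log2(table$values + offset), table$probe_id,
                  table$gene_symbol, table$is_control, state = table$state,
                  log2 = TRUE)
}

#' Quantile-normalize sample columns
#'
#' Forces every sample column onto the common distribution of per-rank
#' column means: sorted value vectors become identical across columns
#' while within-column rank order is preserved. Ties receive the mean of
#' the reference values their positions span. Idempotent.
#'
#' @param table an [intensity_table()] (expected state
#'   `background_corrected`; a raw table is accepted with a warning).
#' @return the normalized table, state `normalized`.
#' @export
quantile_normalize <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$state == "raw")
    warning("quantile normalization on a raw (uncorrected) table")
  x <- table$values
  if (ncol(x) < 2) {
    warning("single sample: quantile normalization is the identity")
    return(intensity_table(x, table$probe_id, table$gene_symbol,
                           table$is_control, state = "normalized",
                           log2 = table$log2))
  }
  ref <- rowMeans(apply(x, 2, sort, method = "radix"))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    col <- numeric(nrow(x))
    col[o] <- ref
    # ties: mean of the reference values the tied positions span
    if (anyDuplicated(x[, j])) {
      col <- stats::ave(col, match(x[, j], x[, j]), FUN = mean)
    }
    out[, j] <- col
  }
  intensity_table(out, table$probe_id, table$gene_symbol, table$is_control,
                  state = "normalized", log2 = table$log2)
}

#' Remove control probes and collapse replicate probes to genes
#'
#' Control probes are removed; probes with an empty gene symbol are dropped
#' (count reported); remaining probes sharing a gene symbol are replaced by
#' their per-sample arithmetic mean (on the log2 scale the table is already
#' on). Row ids of the result are gene symbols, ordered alphabetically.
#'
#' @param table a normalized-state [intensity_table()].
#' @return the collapsed table, state `collapsed`.
#' @export
drop_controls_and_collapse <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$state != "normalized")
    stop("state error: collapsing expects a normalized table, got '",
         table$state, "'")
  keep <- !table$is_control
  if (!any(keep)) stop("table contains only control probes")
  empty <- keep & (is.na(table$gene_symbol) | table$gene_symbol == "")
  if (any(empty)) {
    message(sum(empty), " probe(s) with empty gene symbol dropped")
    keep <- keep & !empty
  }
  if (!any(keep)) stop("no annotated non-control probes left")
  sym <- table$gene_symbol[keep]
  v <- table$values[keep, , drop = FALSE]
  sums <- rowsum(v, sym)                       # sorted by group label
  counts <- as.vector(table(sym)[rownames(sums)])
  out <- sums / counts
  intensity_table(out, rownames(out), rownames(out),
                  rep(FALSE, nrow(out)), state = "collapsed",
                  log2 = table$log2)
}

#' Full preprocessing chain
#'
#' Background correction (normexp conditional expectation by default), log2
#' transform with +1 offset, quantile normalization, then control removal
#' and replicate collapsing — i.e. correction and normalization before
#' probe filtering and averaging.
#'
#' @param table raw-state [intensity_table()].
#' @param method background-correction method, see [background_correct()].
#' @param collapse set `FALSE` to stop after normalization.
#' @return an [intensity_table()] in `collapsed` (or `normalized`) state.
#' @export
preprocess_intensity <- function(table, method = "normexp",
                                 collapse = TRUE) {
  out <- background_correct(table, method = method)
  out <- log2_transform(out)
  out <- quantile_normalize(out)
  if (collapse) out <- drop_controls_and_collapse(out)
  out
}
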