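#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study design the pipeline targets: three groups (ground control C,
#' spaceflight S, post-flight recovery R) with two animals each, genes
#' represented by replicate probes on the array, a fraction of background-only
#' control probes, and expression effects planted in the recovery group so
#' that the R-vs-C and R-vs-S contrasts carry signal while S-vs-C is null.
#'
#' Raw intensities are generated as
#' `X = 2^(baseline_g + effect_{g,group} + N(0, sigma_bio^2)) + B`,
#' with additive background `B ~ N(bg_mu, bg_sigma^2)` (plus an optional
#' `Exp(bg_alpha)` tail when `bg_alpha > 0`), truncated to stay positive.
#' Control probes are background-only.
#'
#' @param n_genes number of gene slots on the array (controls included).
#' @param probes_per_gene replicate probes emitted per gene.
#' @param control_fraction fraction of gene slots that are control probes,
#'   in `[0, 1)`.
#' @param groups ordered group labels.
#' @param n_per_group samples per group.
#' @param n_de number of genes given a planted effect; `NULL` plants 5% of
#'   the non-control genes.
#' @param effect_lfc absolute planted log2 fold change; sign is drawn per
#'   gene.
#' @param effect_group group receiving the planted effects.
#' @param sigma_bio per-probe log2-scale noise SD.
#' @param baseline_mu,baseline_sd log2-scale baseline distribution.
#' @param bg_mu,bg_sigma additive normal background mean and SD
#'   (intensity units).
#' @param bg_alpha optional exponential background scale (0 disables it).
#' @param n_terms,genes_per_term,n_enriched_terms gene-set structure.
#' @param inc_rows,inc_cols incidence-matrix dimensions.
#' @param block_rows,block_cols planted all-ones block dimensions.
#' @param bg_density background one-density of the incidence matrix, in
#'   `[0, 1]`.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, probes_per_gene = 3,
                       control_fraction = 0.05,
                       groups = c("C", "S", "R"), n_per_group = 2,
                       n_de = NULL, effect_lfc = 4, effect_group = "R",
                       sigma_bio = 1, baseline_mu = 12, baseline_sd = 1.5,
                       bg_mu = 80, bg_sigma = 5, bg_alpha = 0,
                       n_terms = 50, genes_per_term = 10,
                       n_enriched_terms = 5,
                       inc_rows = 40, inc_cols = 20,
                       block_rows = 8, block_cols = 4, bg_density = 0.1,
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, probes_per_gene = probes_per_gene,
              control_fraction = control_fraction, groups = groups,
              n_per_group = n_per_group, n_de = n_de,
              effect_lfc = effect_lfc, effect_group = effect_group,
              sigma_bio = sigma_bio, baseline_mu = baseline_mu,
              baseline_sd = baseline_sd, bg_mu = bg_mu,
              bg_sigma = bg_sigma, bg_alpha = bg_alpha, n_terms = n_terms,
              genes_per_term = genes_per_term,
              n_enriched_terms = n_enriched_terms, inc_rows = inc_rows,
              inc_cols = inc_cols, block_rows = block_rows,
              block_cols = block_cols, bg_density = bg_density,
              seed = as.integer(seed))
  if (is.null(cfg$n_de))
    cfg$n_de <- round(0.05 * (n_genes - round(n_genes * control_fraction)))
  counts <- c("n_genes", "probes_per_gene", "n_per_group", "n_terms",
              "genes_per_term", "inc_rows", "inc_cols", "block_rows",
              "block_cols")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop("configuration error: '", f, "' must be a positive count")
  }
  if (cfg$control_fraction < 0 || cfg$control_fraction >= 1)
    stop("configuration error: control_fraction must be in [0, 1)")
  if (cfg$bg_density < 0 || cfg$bg_density > 1)
    stop("configuration error: bg_density must be in [0, 1]")
  if (cfg$n_de < 0) stop("configuration error: n_de must be >= 0")
  n_real <- n_genes - round(n_genes * control_fraction)
  if (cfg$n_de > n_real)
    stop("configuration error: n_de exceeds the number of non-control genes")
  if (cfg$sigma_bio < 0 || cfg$bg_sigma < 0 || cfg$bg_alpha < 0)
    stop("configuration error: scale parameters must be >= 0")
  if (length(groups) < 2) stop("configuration error: need >= 2 groups")
  if (!effect_group %in% groups)
    stop("configuration error: effect_group must be one of the group labels")
  if (cfg$genes_per_term > n_real)
    stop("configuration error: genes_per_term exceeds the gene universe")
  if (cfg$block_rows > cfg$inc_rows || cfg$block_cols > cfg$inc_cols)
    stop("configuration error: planted block exceeds the incidence matrix")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate synthetic probe-level expression data with known truth
#'
#' Emits a raw-state [intensity_table()] with `probes_per_gene` replicate
#' probes per gene, background-only control probes, and effects of size
#' `effect_lfc` (random sign per gene) planted in `effect_group`. The truth
#' object records, per pairwise contrast, the planted genes and their signed
#' log2 fold changes; contrasts not involving `effect_group` are null.
#'
#' @param config a [sim_config()].
#' @return list with elements `table` (the raw `intensity_table`), `design`
#'   (data.frame `sample_id`, `group`) and `truth` (list with `de_genes`,
#'   holding one data.frame of `gene`, `lfc` per contrast).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_ctrl <- round(config$n_genes * config$control_fraction)
  n_real <- config$n_genes - n_ctrl
  genes <- sprintf("G%05d", seq_len(n_real))
  ctrls <- if (n_ctrl > 0) sprintf("CTRL%04d", seq_len(n_ctrl)) else character()

  groups <- rep(config$groups, each = config$n_per_group)
  sample_id <- paste(groups, rep(seq_len(config$n_per_group),
                                 times = length(config$groups)), sep = "_")
  design <- data.frame(sample_id = sample_id, group = groups,
                       stringsAsFactors = FALSE)

  baseline <- stats::rnorm(n_real, config$baseline_mu, config$baseline_sd)
  de_idx <- if (config$n_de > 0) sort(sample.int(n_real, config$n_de)) else integer()
  sign <- sample(c(-1, 1), length(de_idx), replace = TRUE)
  delta <- numeric(n_real)
  delta[de_idx] <- sign * config$effect_lfc

  n_samples <- length(sample_id)
  # log2-scale mean per gene and sample: baseline + effect in effect_group
  mu <- outer(baseline, rep(1, n_samples))
  in_eff <- groups == config$effect_group
  mu[, in_eff] <- mu[, in_eff] + delta

  p <- config$probes_per_gene
  # expand genes to replicate probes; controls appended, signal-free
  probe_gene <- rep(seq_len(n_real), each = p)
  n_gene_probes <- n_real * p
  n_ctrl_probes <- n_ctrl * p
  signal <- 2^(mu[probe_gene, , drop = FALSE] +
                 matrix(stats::rnorm(n_gene_probes * n_samples,
                                     sd = config$sigma_bio),
                        n_gene_probes, n_samples))
  x <- rbind(signal,
             matrix(0, n_ctrl_probes, n_samples))
  bg <- matrix(stats::rnorm(nrow(x) * n_samples, config$bg_mu,
                            config$bg_sigma), nrow(x), n_samples)
  if (config$bg_alpha > 0) {
    bg <- bg + matrix(stats::rexp(nrow(x) * n_samples,
                                  rate = 1 / config$bg_alpha),
                      nrow(x), n_samples)
  }
  x <- pmax(x + bg, 1e-3)
  colnames(x) <- sample_id

  probe_id <- c(paste0(rep(genes, each = p), "_p", rep(seq_len(p), n_real)),
                if (n_ctrl > 0)
                  paste0(rep(ctrls, each = p), "_p", rep(seq_len(p), n_ctrl)))
  gene_symbol <- c(rep(genes, each = p), rep(ctrls, each = p))
  is_control <- c(rep(FALSE, n_gene_probes), rep(TRUE, n_ctrl_probes))

  tab <- intensity_table(x, probe_id, gene_symbol, is_control, state = "raw")

  planted <- data.frame(gene = genes[de_idx], lfc = delta[de_idx],
                        stringsAsFactors = FALSE)
  contrasts <- pairwise_contrast_names(config$groups)
  de_genes <- lapply(contrasts, function(nm) {
    parts <- strsplit(nm, "_vs_")[[1]]
    if (config$effect_group == parts[1]) {
      planted
    } else if (config$effect_group == parts[2]) {
      data.frame(gene = planted$gene, lfc = -planted$lfc,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = character(), lfc = numeric(),
                 stringsAsFactors = FALSE)
    }
  })
  names(de_genes) <- contrasts
  truth <- list(de_genes = de_genes, genes = genes,
                baseline = stats::setNames(baseline, genes))
  list(table = tab, design = design, truth = truth)
}

# contrast names for ordered groups (later vs earlier), e.g. C,S,R ->
# S_vs_C, R_vs_C, R_vs_S
pairwise_contrast_names <- function(groups) {
  out <- character()
  for (j in seq_along(groups)) {
    for (i in seq_len(j - 1L)) {
      out <- c(out, paste0(groups[j], "_vs_", groups[i]))
    }
  }
  out
}

#' Generate a synthetic gene-set collection with planted enriched terms
#'
#' The first `n_enriched_terms` terms draw at least 80% of their members
#' from the planted differentially expressed genes; all other terms draw
#' uniformly from the gene universe. Namespace labels cycle over
#' BP/MF/CC/HP across terms.
#'
#' @param config a [sim_config()].
#' @param truth the truth component returned by [generate_expression()]
#'   under the same config.
#' @return list with `collection` (a [gene_set_collection()]) and
#'   `enriched_terms` (character vector of planted term ids).
#' @export
generate_genesets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  universe <- truth$genes
  de_pool <- unique(unlist(lapply(truth$de_genes, `[[`, "gene")))
  k <- config$genes_per_term
  n_de_members <- ceiling(0.8 * k)
  if (config$n_enriched_terms > 0 && length(de_pool) < n_de_members)
    stop("configuration error: too few planted DE genes to build enriched terms")
  ns_cycle <- c("BP", "MF", "CC", "HP")
  terms <- vector("list", config$n_terms)
  enriched <- character()
  for (i in seq_len(config$n_terms)) {
    id <- sprintf("T%04d", i)
    if (i <= config$n_enriched_terms) {
      members <- c(sample(de_pool, n_de_members),
                   sample(setdiff(universe, de_pool), k - n_de_members))
      enriched <- c(enriched, id)
      name <- sprintf("planted enriched term %d", i)
    } else {
      members <- sample(universe, k)
      name <- sprintf("background term %d", i)
    }
    terms[[i]] <- list(term_id = id, term_name = name,
                       namespace = ns_cycle[(i - 1L) %% 4L + 1L],
                       genes = sort(members))
  }
  list(collection = gene_set_collection(terms), enriched_terms = enriched)
}

#' Generate a binary gene-by-term incidence matrix with a planted block
#'
#' Background cells are i.i.d. Bernoulli(`bg_density`); a `block_rows` x
#' `block_cols` all-ones block is planted at random row/column positions.
#' Row weights (standing in for gene importance scores) are drawn from a
#' lognormal distribution, with the largest `block_rows` weights assigned
#' to the planted rows.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (an [incidence_matrix()]) and `truth`
#'   (`planted_block`: list of `rows`, `cols` ids).
#' @export
generate_incidence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  nr <- config$inc_rows; nc <- config$inc_cols
  rows <- sprintf("g%03d", seq_len(nr))
  cols <- sprintf("t%03d", seq_len(nc))
  B <- matrix(stats::rbinom(nr * nc, 1L, config$bg_density), nr, nc,
              dimnames = list(rows, cols))
  br <- sort(sample.int(nr, config$block_rows))
  bc <- sort(sample.int(nc, config$block_cols))
  B[br, bc] <- 1L
  w <- sort(stats::rlnorm(nr, meanlog = 0, sdlog = 0.5))
  weights <- numeric(nr)
  weights[br] <- w[(nr - config$block_rows + 1L):nr]       # upper quantile
  weights[-br] <- w[seq_len(nr - config$block_rows)][
    sample.int(nr - config$block_rows)]
  names(weights) <- rows
  list(matrix = incidence_matrix(B, weights),
       truth = list(planted_block = list(rows = rows[br], cols = cols[bc])))
}
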