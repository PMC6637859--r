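#' Pipeline configuration
#'
#' Collects every parameter of the end-to-end synthetic pipeline. The
#' analysis thresholds default to the study's: adjusted p < 0.05 and
#' |log2 fold change| > 2 for DE calls; top 1,000 genes by Gini score;
#' biological-process terms with permutation p < 0.01 and mapped count
#' >= 10 for the hot-spot input.
#'
#' @param out_dir output directory (created if missing).
#' @param seed global integer seed, fanned out to per-stage seeds by
#'   [stage_seed()].
#' @param sim a [sim_config()]; its own seed is overridden by the stage
#'   seed.
#' @param p_thresh,lfc_thresh DE cutoffs.
#' @param n_top,term_p_thresh,min_count enrichment filters.
#' @param gamma hot-spot zero penalty.
#' @param n_trees random-forest size.
#' @param n_perm permutations per term score.
#' @param top_k heatmap panel size.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(),
                            p_thresh = 0.05, lfc_thresh = 2,
                            n_top = 1000, term_p_thresh = 0.01,
                            min_count = 10, gamma = 1, n_trees = 1000,
                            n_perm = 1000, top_k = 50) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              p_thresh = p_thresh, lfc_thresh = lfc_thresh, n_top = n_top,
              term_p_thresh = term_p_thresh, min_count = min_count,
              gamma = gamma, n_trees = n_trees, n_perm = n_perm,
              top_k = top_k)
  if (cfg$p_thresh <= 0 || cfg$p_thresh > 1)
    stop("validation error: p_thresh must be in (0, 1]")
  if (cfg$lfc_thresh < 0)
    stop("validation error: lfc_thresh must be >= 0")
  if (cfg$term_p_thresh <= 0 || cfg$min_count < 1 || cfg$n_top < 1 ||
      cfg$gamma < 0 || cfg$n_trees < 1 || cfg$n_perm < 1)
    stop("validation error: thresholds must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Per-stage seed derived from the global seed
#'
#' Deterministic fan-out `(seed * 101 + stage * 7919) mod (2^31 - 1)` so
#' that any stage can be rerun in isolation with the seed recorded in the
#' manifest.
#'
#' @param seed global integer seed.
#' @param stage stage index (1-based).
#' @return integer stage seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 101 + as.numeric(stage) * 7919) %%
               2147483647)
}

#' Run the full synthetic pipeline
#'
#' Executes, in order: (1) simulation of expression data, design, and gene
#' sets; (2) preprocessing (background correction, log2, quantile
#' normalization, control removal, replicate collapsing); (3) differential
#' expression with moderated t-statistics, BH adjustment and the DE
#' cutoffs; (4) exploratory structure (sample dendrogram, PCA, top-gene
#' heatmap ordering); (5) enrichment (hypergeometric overrepresentation of
#' the DE union; random-forest Gini importance aggregated over terms with
#' permutation p-values and the top-gene/term filters); (6) hot-spot
#' detection on the selected gene x term incidence matrix. Every stage
#' writes TSVs under `out_dir` and a manifest records parameters and
#' per-stage seeds; identical config + seed reruns are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the per-stage result objects and the
#'   manifest path.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list()
  note <- function(stage, idx, ...) {
    manifest[[stage]] <<- data.frame(stage = stage,
                                     seed = stage_seed(config$seed, idx),
                                     status = "completed",
                                     params = paste(..., sep = "; "),
                                     stringsAsFactors = FALSE)
  }

  # 1 simulate
  sim <- config$sim
  sim$seed <- stage_seed(config$seed, 1L)
  gen <- generate_expression(sim)
  gs <- generate_genesets(sim, gen$truth)
  write_expression_tsv(gen$table, out("expression_raw.tsv"))
  write_design(gen$design, out("design.tsv"))
  write_gmt(gs$collection, out("genesets.gmt"))
  truth_de <- do.call(rbind, lapply(names(gen$truth$de_genes), function(nm) {
    df <- gen$truth$de_genes[[nm]]
    if (nrow(df) == 0) return(NULL)
    cbind(contrast = nm, df)
  }))
  if (is.null(truth_de))
    truth_de <- data.frame(contrast = character(), gene = character(),
                           lfc = numeric())
  write_results(truth_de, out("truth_de_genes.tsv"))
  writeLines(gs$enriched_terms, out("truth_enriched_terms.txt"))
  note("simulate", 1L, sprintf("n_genes=%d", sim$n_genes),
       sprintf("n_de=%d", sim$n_de))

  # 2 preprocess
  collapsed <- preprocess_intensity(gen$table)
  write_expression_tsv(collapsed, out("expression_collapsed.tsv"))
  note("preprocess", 2L, "bg=normexp", "log2 offset=1", "quantile")

  # 3 differential expression
  fit <- fit_models(collapsed, gen$design)
  prior <- estimate_prior(fit)
  stats <- moderate_and_test(fit, prior)
  calls <- call_de(stats, config$p_thresh, config$lfc_thresh)
  for (nm in unique(stats$contrast)) {
    write_results(volcano_table(stats, nm, config$p_thresh,
                                config$lfc_thresh),
                  out(paste0("volcano_", nm, ".tsv")))
  }
  write_results(stats, out("moderated_stats.tsv"))
  write_results(calls$summary, out("de_summary.tsv"))
  note("de", 3L, sprintf("p_fdr<%g", config$p_thresh),
       sprintf("|log2FC|>%g", config$lfc_thresh),
       sprintf("d0=%.6g", prior$d0))

  # 4 explore
  samples_x_genes <- t(collapsed$values)
  hc <- hclust_complete(samples_x_genes)
  ape::write.tree(ape::as.phylo(hc), out("sample_dendrogram.nwk"))
  pc <- pca_samples(samples_x_genes)
  write_results(data.frame(sample_id = rownames(pc$scores),
                           as.data.frame(pc$scores)),
                out("pca_scores.tsv"))
  top <- top_k_table(stats, min(config$top_k, nrow(collapsed$values)))
  ord <- heatmap_order(collapsed$values[top, , drop = FALSE])
  write_results(data.frame(row_rank = seq_along(ord$row_ids),
                           gene = ord$row_ids),
                out("heatmap_row_order.tsv"))
  note("explore", 4L, "linkage=complete", "distance=euclidean",
       sprintf("top_k=%d", config$top_k))

  # 5 enrich
  universe <- collapsed$probe_id
  de_union <- sort(unique(unlist(lapply(
    calls[setdiff(names(calls), "summary")], unlist))))
  ora_res <- if (length(de_union)) {
    ora(de_union, universe, gs$collection)
  } else {
    data.frame()
  }
  write_results(ora_res, out("ora_results.tsv"))
  imp <- rf_importance(collapsed, gen$design, n_trees = config$n_trees,
                       seed = stage_seed(config$seed, 5L))
  write_results(imp, out("gini_importance.tsv"))
  terms <- aggregate_terms(imp, gs$collection)
  terms <- add_permutation_p(terms, imp, n_perm = config$n_perm,
                             seed = stage_seed(config$seed, 5L))
  write_results(terms, out("term_scores.tsv"))
  sel <- filter_and_select(terms, imp, n_top = min(config$n_top, nrow(imp)),
                           p_thresh = config$term_p_thresh,
                           min_count = config$min_count)
  writeLines(sel$genes, out("selected_genes.txt"))
  write_results(sel$terms, out("selected_terms.tsv"))
  note("enrich", 5L, sprintf("n_trees=%d", config$n_trees),
       sprintf("n_perm=%d", config$n_perm),
       sprintf("top=%d", config$n_top),
       sprintf("term p<%g, count>=%d", config$term_p_thresh,
               config$min_count))

  # 6 hotspot
  hot <- NULL
  if (nrow(sel$terms) > 0) {
    B <- vapply(sel$terms$term_id, function(tid)
      as.integer(sel$genes %in% gs$collection[[tid]]$genes),
      integer(length(sel$genes)))
    if (!is.matrix(B)) B <- matrix(B, nrow = length(sel$genes))
    dimnames(B) <- list(sel$genes, sel$terms$term_id)
    keep <- rowSums(B) > 0
    if (any(keep)) {
      w <- stats::setNames(imp$importance, imp$gene)[sel$genes[keep]]
      M <- incidence_matrix(B[keep, , drop = FALSE], w)
      hot <- alternate_maximize(M, hotspot_params(gamma = config$gamma))
      rep <- report_hotspot(hot, M)
      write_results(rep$edges, out("hotspot_edges.tsv"))
      writeLines(c(rep$summary,
                   paste("genes:", paste(hot$genes, collapse = ",")),
                   paste("terms:", paste(hot$terms, collapse = ","))),
                 out("hotspot_summary.txt"))
    }
  }
  if (is.null(hot)) {
    write_results(data.frame(gene = character(), term = character(),
                             weight = numeric()), out("hotspot_edges.tsv"))
    writeLines("0 genes linked with 0 terms", out("hotspot_summary.txt"))
  }
  note("hotspot", 6L, sprintf("gamma=%g", config$gamma))

  manifest_df <- do.call(rbind, manifest)
  manifest_df <- cbind(manifest_df,
                       global_seed = config$seed,
                       package_version = as.character(
                         utils::packageVersion("spacecord")))
  write_results(manifest_df, out("manifest.tsv"))
  invisible(list(truth = gen$truth, collapsed = collapsed, stats = stats,
                 calls = calls, ora = ora_res, importance = imp,
                 terms = terms, selection = sel, hotspot = hot,
                 manifest = out("manifest.tsv")))
}
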