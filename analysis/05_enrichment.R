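#!/usr/bin/env Rscript
# Stage 5 -- two enrichment engines: (a) hypergeometric overrepresentation
# of the DE union against the gene-set collection (BH within namespace);
# (b) random-forest Gini importance of genes for the group classification,
# aggregated per term, with permutation p-values and the study filters
# (top 1,000 genes; BP terms with p < 0.01 and >= 10 mapped genes).
suppressMessages(library(spacecord))

seed <- 20190711L
collapsed <- read_expression_tsv("results/expression_collapsed.tsv")
design <- read_design("results/data/design.tsv")
collection <- read_gmt("results/data/genesets.gmt")
stats <- utils::read.delim("results/moderated_stats.tsv")
calls <- call_de(stats)

de_union <- sort(unique(unlist(
  lapply(calls[setdiff(names(calls), "summary")], unlist))))
message(length(de_union), " genes in the DE union")
ora_res <- ora(de_union, collapsed$probe_id, collection)
write_results(ora_res, "results/ora_results.tsv")
message(sprintf("ORA: %d terms tested, %d with p_FDR < 0.05",
                nrow(ora_res), sum(ora_res$p_fdr < 0.05)))

imp <- rf_importance(collapsed, design, n_trees = 1000, seed = seed + 1L)
write_results(imp, "results/gini_importance.tsv")
terms <- aggregate_terms(imp, collection)
terms <- add_permutation_p(terms, imp, n_perm = 1000, seed = seed + 2L)
write_results(terms, "results/term_scores.tsv")

sel <- filter_and_select(terms, imp, n_top = 1000,
                         p_thresh = 0.01, min_count = 10)
writeLines(sel$genes, "results/selected_genes.txt")
write_results(sel$terms, "results/selected_terms.tsv")
message(sprintf("selected %d genes and %d BP terms for hot-spot detection",
                length(sel$genes), nrow(sel$terms)))
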