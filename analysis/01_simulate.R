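#!/usr/bin/env Rscript
# Stage 1 -- simulate the study: 3 groups (C ground control, S spaceflight,
# R 7-day recovery) x 2 animals, ~10,000 genes as triplicate probes with
# background-only control probes, 300 genes planted at |log2FC| = 4 in the
# recovery group, and a gene-set collection with 5 planted enriched terms.
suppressMessages(library(spacecord))

seed <- 20190711L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_genes = 10000, n_de = 300, effect_lfc = 4,
                  sigma_bio = 1, n_terms = 50, genes_per_term = 10,
                  n_enriched_terms = 5, seed = seed)
gen <- generate_expression(cfg)
gs <- generate_genesets(cfg, gen$truth)

write_expression_tsv(gen$table, "results/data/expression_raw.tsv")
write_design(gen$design, "results/data/design.tsv")
write_gmt(gs$collection, "results/data/genesets.gmt")
truth <- do.call(rbind, lapply(names(gen$truth$de_genes), function(nm) {
  df <- gen$truth$de_genes[[nm]]
  if (nrow(df)) cbind(contrast = nm, df)
}))
write_results(truth, "results/data/truth_de_genes.tsv")
writeLines(gs$enriched_terms, "results/data/truth_enriched_terms.txt")

message(sprintf(
  "simulated %d probes x %d samples (%d control probes), %d planted DE genes, %d gene sets (%d enriched)",
  nrow(gen$table$values), ncol(gen$table$values),
  sum(gen$table$is_control), cfg$n_de, cfg$n_terms, cfg$n_enriched_terms))
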