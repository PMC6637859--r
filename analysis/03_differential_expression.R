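#!/usr/bin/env Rscript
# Stage 3 -- moderated differential expression over the three pairwise
# comparisons (S vs C, R vs C, R vs S): per-gene group-means OLS,
# empirical-Bayes variance moderation, BH adjustment per contrast, and the
# study cutoffs p_FDR < 0.05 and |log2FC| > 2.
suppressMessages(library(spacecord))

collapsed <- read_expression_tsv("results/expression_collapsed.tsv")
design <- read_design("results/data/design.tsv")

fit <- fit_models(collapsed, design)
prior <- estimate_prior(fit)
stats <- moderate_and_test(fit, prior)
calls <- call_de(stats, p_thresh = 0.05, lfc_thresh = 2)

write_results(stats, "results/moderated_stats.tsv")
write_results(calls$summary, "results/de_summary.tsv")
for (nm in unique(stats$contrast)) {
  write_results(volcano_table(stats, nm),
                sprintf("results/volcano_%s.tsv", nm))
}
writeLines(top_k_table(stats, 50), "results/top50_genes.txt")

message(sprintf("prior: d0 = %.3g, s0^2 = %.3g", prior$d0, prior$s02))
for (i in seq_len(nrow(calls$summary))) {
  message(sprintf("%s: %d up, %d down", calls$summary$contrast[i],
                  calls$summary$n_up[i], calls$summary$n_down[i]))
}
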