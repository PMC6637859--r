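#!/usr/bin/env Rscript
# Stage 4 -- exploratory sample structure: complete-linkage Euclidean
# clustering of the six arrays, PCA of the collapsed profiles, and two-way
# dendrogram ordering of the top-50 DE heatmap panel.
suppressMessages(library(spacecord))

collapsed <- read_expression_tsv("results/expression_collapsed.tsv")
x <- t(collapsed$values)

hc <- hclust_complete(x)
ape::write.tree(ape::as.phylo(hc), "results/sample_dendrogram.nwk")
ct <- cut_clusters(hc, 2)
message("two-cluster cut: ",
        paste(sprintf("%s=%d", names(ct), ct), collapse = " "))

pc <- pca_samples(x)
write_results(data.frame(sample_id = rownames(pc$scores), pc$scores),
              "results/pca_scores.tsv")
message(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of variance",
                100 * pc$var_explained[1], 100 * pc$var_explained[2]))

top <- readLines("results/top50_genes.txt")
ord <- heatmap_order(collapsed$values[top, , drop = FALSE])
write_results(data.frame(row_rank = seq_along(ord$row_ids),
                         gene = ord$row_ids),
              "results/heatmap_row_order.tsv")
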