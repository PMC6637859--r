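#!/usr/bin/env Rscript
# Stage 2 -- preprocessing: normexp background correction (parameters from
# the control probes), log2(x+1), quantile normalization across the six
# arrays, then control-probe removal and replicate collapsing to genes.
suppressMessages(library(spacecord))

raw <- read_expression_tsv("results/data/expression_raw.tsv")
collapsed <- preprocess_intensity(raw)
write_expression_tsv(collapsed, "results/expression_collapsed.tsv")

message(sprintf("collapsed %d probes to %d genes x %d samples",
                nrow(raw$values), nrow(collapsed$values),
                ncol(collapsed$values)))
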