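#!/usr/bin/env Rscript
# Normalize and filter the raw matrix: quantile normalization across samples,
# presence-call and per-state variance filters, then per-gene Z-scores.
library(dvcscan)

dat <- "results/data"
inp <- read_expression(file.path(dat, "expression.tsv"),
                       file.path(dat, "sample_sheet.tsv"))
calls_tab <- read.delim(file.path(dat, "calls.tsv"), check.names = FALSE)
calls <- as.matrix(calls_tab[, -1])
rownames(calls) <- calls_tab$gene

norm <- quantile_normalize(inp$matrix)
norm <- filter_genes(norm, inp$design, calls = calls, presence_frac = 0.5)
z <- zscore_genes(norm)

write_expression(norm, file.path(dat, "expression_normalized.tsv"))
write_expression(z, file.path(dat, "expression_zscored.tsv"))
message(sprintf("retained %d of %d genes after filtering", nrow(norm),
                nrow(inp$matrix)))
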