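#!/usr/bin/env Rscript
# Companion differential analysis: Welch t-tests and the fold-change rule for
# DE genes, F-tests for differentially variable (DV) genes, BH adjustment
# within each state's family.
library(dvcscan)

dat <- "results/data"
out <- "results"
inp <- read_expression(file.path(dat, "expression_normalized.tsv"),
                       file.path(dat, "sample_sheet.tsv"))

res <- diff_expression(inp$matrix, inp$design, alpha = 0.05, fc_k = 2)

write.table(res$table, file.path(out, "diffexpr.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(res$de_genes, file.path(out, "de_genes.txt"))
writeLines(res$dv_genes, file.path(out, "dv_genes.txt"))

truth <- read.delim(file.path(dat, "truth.tsv"))
de_true <- truth$gene[truth$de == 1]
message(sprintf("DE sensitivity on planted DE genes: %.3f",
                mean(de_true %in% res$de_genes)))

dvc <- readLines(file.path(out, "dvc_genes.txt"))
jac <- length(intersect(res$de_genes, dvc)) /
  max(1, length(union(res$de_genes, dvc)))
message(sprintf("DE/DVC Jaccard overlap: %.3f (the calls target disjoint gene populations)",
                jac))
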