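#!/usr/bin/env Rscript
# Enrichment and cross-dataset overlap: (i) which module concentrates the
# variance-changed (DV) genes; (ii) hypergeometric overlap of DVC calls from
# two independently simulated datasets, linked through an ortholog-style
# identity map — the two-species comparison on ground-truthed data.
library(dvcscan)

dat <- "results/data"
out <- "results"
inp <- read_expression(file.path(dat, "expression_zscored.tsv"),
                       file.path(dat, "sample_sheet.tsv"))
mod_tab <- read.delim(file.path(dat, "modules.tsv"))
modules <- setNames(mod_tab$module, mod_tab$gene)
dv <- readLines(file.path(out, "dv_genes.txt"))

flags <- setNames(rownames(inp$matrix) %in% dv, rownames(inp$matrix))
enr <- module_enrichment(flags, modules)
write.table(enr, file.path(out, "module_dv_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("module most enriched in DV genes: ", enr$set[1],
        sprintf(" (p = %.3g)", enr$p[1]))

# second "species": an independent replicate study of the same system
run_dvc <- function(seed) {
  res <- run_pipeline(sim_config(seed = seed))
  list(dvc = res$dvc$genes, universe = res$scores$gene)
}
a <- run_dvc(17)
b <- run_dvc(99)
map <- data.frame(a = sprintf("gene%04d", 1:1160),
                  b = toupper(sprintf("gene%04d", 1:1160)))
ov <- ortholog_overlap_test(a$dvc, toupper(b$dvc), map,
                            a$universe, toupper(b$universe))
write.table(ov, file.path(out, "cross_dataset_overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "cross-dataset DVC overlap: %d of %d vs %d in a universe of %d, p = %.3g",
  ov$overlap, ov$query_size, ov$annotated, ov$universe_size, ov$p))
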