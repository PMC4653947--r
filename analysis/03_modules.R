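#!/usr/bin/env Rscript
# Detect co-expression modules at the reference state: 1 - PCC distances over
# the reference replicates, average linkage, hybrid dynamic tree cut.
library(dvcscan)

dat <- "results/data"
inp <- read_expression(file.path(dat, "expression_zscored.tsv"),
                       file.path(dat, "sample_sheet.tsv"))

modules <- detect_modules(inp$matrix, inp$design, min_size = 100)

df <- data.frame(gene = names(modules), module = unname(modules))
write.table(df, file.path(dat, "modules.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.delim(file.path(dat, "truth.tsv"))
tab <- table(detected = modules[truth$gene], planted = truth$module)
message("detected x planted module cross-tabulation:")
print(tab)
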