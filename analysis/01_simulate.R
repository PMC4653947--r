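#!/usr/bin/env Rscript
# Generate the reference synthetic differentiation time course: two transition
# modules whose latent factor collapses after the undifferentiated state, one
# stable module, independent background genes, and planted DE genes.
library(dvcscan)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config()          # 1160 genes, 4 states x 8 replicates, seed 17
sim <- simulate_dataset(cfg)

write_expression(sim$matrix, file.path(out, "expression.tsv"))
write_sample_sheet(sim$design, file.path(out, "sample_sheet.tsv"))
write_truth(sim$truth, file.path(out, "truth.tsv"))
calls <- simulate_presence_calls(sim$matrix, absent_fraction = 0.02,
                                 seed = cfg$seed)
write.table(data.frame(gene = rownames(calls), calls, check.names = FALSE),
            file.path(out, "calls.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("wrote %d genes x %d samples (%d transition, %d DE) to %s",
                nrow(sim$matrix), ncol(sim$matrix),
                length(sim$truth$transition_genes),
                length(sim$truth$de_genes), out))
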