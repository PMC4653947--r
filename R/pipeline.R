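#' Run the full analysis pipeline on a synthetic dataset
#'
#' End-to-end driver (the "run-all"): generates a synthetic time course,
#' preprocesses it (quantile normalization, per-state variance filter, per-gene
#' Z-scores), detects reference-state co-expression modules, computes per-state
#' statistics and system transition scores, calls DVC genes, runs the
#' companion differential expression/variance analysis, tests per-module
#' enrichment of variance-changed genes, and exports the DVC co-expression
#' network. Every output table is written as deterministic TSV, so two runs
#' with the same config are byte-identical.
#'
#' @param config a [sim_config()]; its seed fixes all randomness.
#' @param out_dir output directory (created if needed); NULL writes nothing.
#' @param min_size,deep_split passed to [detect_modules()].
#' @param epsilon index floor, passed to scoring.
#' @param alpha,fc_k passed to [diff_expression()].
#' @param sd_k DVC threshold multiplier, passed to [call_dvc()].
#' @param network_threshold correlation cutoff for the exported network.
#' @return (invisibly) a list with all intermediate objects: `matrix`,
#'   `design`, `truth`, `normalized`, `zscored`, `modules`, `stats`, `scores`,
#'   `dvc`, `diff`, `dynamics`, `module_dv_enrichment`, `network`,
#'   `state_summary`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         min_size = 100, deep_split = 1, epsilon = 1e-6,
                         alpha = 0.05, fc_k = 2, sd_k = 2,
                         network_threshold = 0.95) {
  sim <- simulate_dataset(config)
  x <- sim$matrix
  design <- sim$design

  normalized <- quantile_normalize(x)
  normalized <- filter_genes(normalized, design)
  zscored <- zscore_genes(normalized)

  modules <- detect_modules(zscored, design, min_size = min_size,
                            deep_split = deep_split)
  stats_tab <- state_statistics(zscored, design, modules, epsilon = epsilon)
  scores <- transition_score(stats_tab, design, epsilon = epsilon)
  dvc <- call_dvc(scores, k = sd_k)
  state_summary <- max_change_state_summary(dvc)

  diff <- diff_expression(normalized, design, alpha = alpha, fc_k = fc_k)
  dynamics <- dynamics_table(stats_tab, design,
                             fold_changes = diff$table, epsilon = epsilon)

  dv_flags <- stats::setNames(rownames(zscored) %in% diff$dv_genes,
                              rownames(zscored))
  module_dv <- if (any(modules != 0)) module_enrichment(dv_flags, modules) else NULL

  network <- export_module_network(zscored, design, modules, dvc$genes,
                                   state = reference_state(design),
                                   threshold = network_threshold)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_expression(x, p("expression.tsv"))
    write_sample_sheet(design, p("sample_sheet.tsv"))
    write_truth(sim$truth, p("truth.tsv"))
    write_expression(zscored, p("expression_zscored.tsv"))
    write_tsv(data.frame(gene = names(modules), module = unname(modules),
                         stringsAsFactors = FALSE), p("modules.tsv"))
    write_tsv(stats_tab, p("state_stats.tsv"))
    write_tsv(dynamics, p("dynamics.tsv"))
    sc <- dvc$flags
    sc$dvc <- as.integer(sc$dvc)
    write_tsv(sc, p("scores.tsv"))
    writeLines(dvc$genes, p("dvc_genes.txt"))
    write_tsv(diff$table, p("diffexpr.tsv"))
    writeLines(diff$de_genes, p("de_genes.txt"))
    writeLines(diff$dv_genes, p("dv_genes.txt"))
    if (!is.null(module_dv)) write_tsv(module_dv, p("module_dv_enrichment.tsv"))
    write_edge_list(network, p("network.tsv"))
    if (length(state_summary)) {
      write_tsv(data.frame(state = names(state_summary),
                           fraction = as.numeric(state_summary),
                           stringsAsFactors = FALSE), p("argmax_summary.tsv"))
    }
  }

  invisible(list(matrix = x, design = design, truth = sim$truth,
                 normalized = normalized, zscored = zscored,
                 modules = modules, stats = stats_tab, scores = scores,
                 dvc = dvc, diff = diff, dynamics = dynamics,
                 module_dv_enrichment = module_dv, network = network,
                 state_summary = state_summary))
}
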