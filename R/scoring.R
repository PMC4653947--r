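#' Per-state gene statistics (SD, module PCC, outside-module PCC)
#'
#' For each gene with a nonzero module label and each state, computes the
#' sample SD across the state's replicates, the mean absolute Pearson
#' correlation with the other genes of its module (mpcc), the mean absolute
#' correlation with all genes outside the module (opcc), and the composite
#' index I = mpcc * sd / max(opcc, epsilon). All correlations are computed
#' within the state's replicates only. Absolute correlations are used for both
#' averages: a signed outside-module average is ~0 and makes the denominator
#' degenerate (`signed_pcc = TRUE` restores the signed reading).
#'
#' @param x expression matrix (genes x samples).
#' @param design a [sample_design()]; every state needs >= 3 replicates.
#' @param modules named integer module labels over the genes of `x`
#'   (0 = unassigned; such genes still serve as outside-module partners but
#'   receive no rows).
#' @param epsilon floor for the opcc denominator; default 1e-6.
#' @param signed_pcc average signed instead of absolute correlations.
#' @return data frame with columns `gene`, `state`, `sd`, `mpcc`, `opcc`,
#'   `index`; one row per scored gene per state, states in design order.
#' @export
state_statistics <- function(x, design, modules, epsilon = 1e-6,
                             signed_pcc = FALSE) {
  check_matrix_design(x, design)
  if (!all(rownames(x) %in% names(modules))) {
    stop("modules must label every gene of the matrix")
  }
  modules <- modules[rownames(x)]
  if (all(modules == 0)) stop("modules nonempty required: all labels are 0")
  sizes <- table(modules[modules != 0])
  if (any(sizes < 2)) {
    stop("module(s) of size 1 cannot form a within-module PCC: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  states <- design_states(design)
  scored <- which(modules != 0)
  G <- nrow(x)
  out <- vector("list", length(states))
  for (si in seq_along(states)) {
    cols <- state_samples(design, states[si])
    if (length(cols) < 3) {
      stop("state '", states[si], "' has < 3 replicates")
    }
    xs <- x[, cols, drop = FALSE]
    sds <- row_sds(xs)
    r <- stats::cor(t(xs))
    if (!signed_pcc) r <- abs(r)
    diag(r) <- 0
    all_sums <- rowSums(r)
    mpcc <- opcc <- rep(NA_real_, G)
    for (m in sort(unique(modules[scored]))) {
      idx <- which(modules == m)
      within <- rowSums(r[idx, idx, drop = FALSE])
      mpcc[idx] <- within / (length(idx) - 1)
      n_out <- G - length(idx)
      opcc[idx] <- if (n_out > 0) (all_sums[idx] - within) / n_out else 0
    }
    out[[si]] <- data.frame(gene = rownames(x)[scored],
                            state = states[si],
                            sd = sds[scored],
                            mpcc = mpcc[scored],
                            opcc = opcc[scored],
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  res$index <- res$mpcc * res$sd / pmax(res$opcc, epsilon)
  attr(res, "epsilon") <- epsilon
  res
}

#' System transition score
#'
#' For each gene, the maximum over post-reference states of the natural-log
#' ratio of composite indices, `max_s log(I_ref / I_s)` with both indices
#' floored at `epsilon`. High scores mark genes that were variable and tightly
#' module-coupled at the reference state and lost both properties afterwards.
#' Ties in the argmax are broken by the earliest state in the design order.
#'
#' @param stats a [state_statistics()] table containing the reference and at
#'   least one other state.
#' @param design the matching [sample_design()].
#' @param epsilon floor inside the log; default 1e-6.
#' @return data frame with columns `gene`, `score`, `argmax_state`.
#' @export
transition_score <- function(stats, design, epsilon = 1e-6) {
  ref <- reference_state(design)
  states <- design_states(design)
  post <- setdiff(states, ref)
  if (!length(post)) stop("need at least one post-reference state")
  genes <- unique(stats$gene)
  idx <- matrix(NA_real_, length(genes), length(states),
                dimnames = list(genes, states))
  for (s in intersect(states, unique(stats$state))) {
    sub <- stats[stats$state == s, ]
    idx[sub$gene, s] <- sub$index
  }
  if (anyNA(idx)) {
    stop("gene(s) missing a state row in the statistics table")
  }
  lr <- log(pmax(idx[, ref], epsilon) / pmax(idx[, post, drop = FALSE], epsilon))
  lr <- matrix(lr, ncol = length(post), dimnames = list(genes, post))
  amax <- apply(lr, 1, which.max)
  data.frame(gene = genes,
             score = lr[cbind(seq_along(genes), amax)],
             argmax_state = post[amax],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call DVC genes from transition scores
#'
#' Flags genes whose score exceeds the mean plus `k` sample SDs of all scores.
#' If every score is identical (SD = 0) the call set is empty.
#'
#' @param scores a [transition_score()] table (>= 2 genes).
#' @param k SD multiplier; default 2.
#' @return list with `genes` (flagged gene ids), `threshold`, and `flags`
#'   (the score table with a logical `dvc` column).
#' @export
call_dvc <- function(scores, k = 2) {
  if (nrow(scores) < 2) stop("need >= 2 scored genes")
  s <- scores$score
  threshold <- mean(s) + k * stats::sd(s)
  flags <- scores
  flags$dvc <- s > threshold
  if (stats::sd(s) == 0) {
    message("call_dvc: all scores identical; empty call set")
  }
  list(genes = scores$gene[flags$dvc], threshold = threshold, flags = flags)
}

#' Distribution of the state of maximal change among DVC genes
#'
#' @param dvc result of [call_dvc()].
#' @return named numeric vector: per state, the fraction of DVC genes whose
#'   argmax state is that state (sums to 1); empty when there are no DVC
#'   genes.
#' @export
max_change_state_summary <- function(dvc) {
  flagged <- dvc$flags[dvc$flags$dvc, , drop = FALSE]
  if (!nrow(flagged)) {
    message("max_change_state_summary: no DVC genes")
    return(stats::setNames(numeric(0), character(0)))
  }
  tab <- table(flagged$argmax_state)
  tab / sum(tab)
}

#' Per-gene differential dynamics table
#'
#' For each scored gene and each post-reference state: differential variance
#' `dvar = |sd_s - sd_ref|`, differential correlation
#' `dcor = |mpcc_s - mpcc_ref|`, and the per-state log index ratio
#' `log_ratio = log(I_ref / I_s)` (epsilon-floored). Optionally joins per-state
#' log2 fold changes from [diff_expression()].
#'
#' @param stats a [state_statistics()] table.
#' @param design the matching [sample_design()].
#' @param fold_changes optional data frame with columns `gene`, `state`,
#'   `log_fc`.
#' @param epsilon floor inside the log; default 1e-6.
#' @return data frame with columns `gene`, `state`, `dvar`, `dcor`,
#'   `log_ratio` (and `log_fc` when supplied).
#' @export
dynamics_table <- function(stats, design, fold_changes = NULL,
                           epsilon = 1e-6) {
  ref <- reference_state(design)
  post <- setdiff(design_states(design), ref)
  refs <- stats[stats$state == ref, ]
  rest <- stats[stats$state %in% post, ]
  m <- match(rest$gene, refs$gene)
  out <- data.frame(gene = rest$gene, state = rest$state,
                    dvar = abs(rest$sd - refs$sd[m]),
                    dcor = abs(rest$mpcc - refs$mpcc[m]),
                    log_ratio = log(pmax(refs$index[m], epsilon) /
                                      pmax(rest$index, epsilon)),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(fold_changes)) {
    key <- match(paste(out$gene, out$state),
                 paste(fold_changes$gene, fold_changes$state))
    out$log_fc <- fold_changes$log_fc[key]
  }
  out
}

#' Export a within-module co-expression network
#'
#' Edges connect gene pairs of the same module, restricted to `genes`, whose
#' signed Pearson correlation within the given state's replicates is at least
#' `threshold`.
#'
#' @param x expression matrix.
#' @param design a [sample_design()].
#' @param modules named module labels.
#' @param genes genes to include (e.g. the DVC set).
#' @param state state whose replicates define the correlations.
#' @param threshold minimum correlation; default 0.95.
#' @return data frame with columns `source`, `target`, `pcc` (canonical pair
#'   order); empty when `genes` is empty.
#' @export
export_module_network <- function(x, design, modules, genes, state,
                                  threshold = 0.95) {
  if (!state %in% design_states(design)) stop("unknown state: ", state)
  genes <- intersect(genes, rownames(x))
  genes <- genes[modules[genes] != 0]
  if (!length(genes)) {
    message("export_module_network: empty gene filter; empty edge list")
    return(data.frame(source = character(0), target = character(0),
                      pcc = numeric(0), stringsAsFactors = FALSE))
  }
  cols <- state_samples(design, state)
  r <- stats::cor(t(x[genes, cols, drop = FALSE]))
  edges <- list()
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (j <= i) next
      if (modules[genes[i]] != modules[genes[j]]) next
      if (r[i, j] >= threshold) {
        edges[[length(edges) + 1]] <- data.frame(
          source = genes[i], target = genes[j], pcc = r[i, j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(edges)) {
    return(data.frame(source = character(0), target = character(0),
                      pcc = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, edges)
}
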