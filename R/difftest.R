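#' Per-gene Welch t-test of one state against the reference
#'
#' Two-sided Welch unequal-variance t-test of each gene's mean between the
#' replicates of `state` and of the reference, with Welch-Satterthwaite
#' degrees of freedom. Degenerate conventions: if both groups have zero
#' variance, p = 1 for equal means and p = 0 otherwise (reported via a
#' message).
#'
#' @param x expression matrix (log2 scale).
#' @param design a [sample_design()]; both groups need >= 2 replicates.
#' @param state the non-reference state to compare.
#' @return data frame with columns `gene`, `log_fc` (mean_state - mean_ref),
#'   `t`, `df`, `p`.
#' @export
welch_t <- function(x, design, state) {
  ref <- reference_state(design)
  if (state == ref) stop("state must differ from the reference")
  a <- x[, state_samples(design, state), drop = FALSE]
  b <- x[, state_samples(design, ref), drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stop("both groups need >= 2 replicates")
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degen <- se2 == 0
  if (any(degen)) {
    message("welch_t: ", sum(degen), " gene(s) with zero variance in both ",
            "groups; p set to 1 (equal means) or 0")
    eq <- degen & (ma == mb)
    t[degen] <- 0
    df[degen] <- na + nb - 2
    p[eq] <- 1
    p[degen & !eq] <- 0
    t[degen & !eq] <- sign(ma - mb)[degen & !eq] * Inf
  }
  data.frame(gene = rownames(x), log_fc = ma - mb, t = t, df = df, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene F-test of differential variance against the reference
#'
#' Variance-ratio test F = s_state^2 / s_ref^2 with two-sided p-value
#' `2 * min(P(F <= f), P(F >= f))` capped at 1, on (n_state - 1, n_ref - 1)
#' degrees of freedom.
#'
#' @param x expression matrix.
#' @param design a [sample_design()]; both groups need >= 2 replicates and the
#'   reference variance must be positive for every gene.
#' @param state the non-reference state to compare.
#' @return data frame with columns `gene`, `f`, `df1`, `df2`, `p`.
#' @export
f_test_variance <- function(x, design, state) {
  ref <- reference_state(design)
  if (state == ref) stop("state must differ from the reference")
  a <- x[, state_samples(design, state), drop = FALSE]
  b <- x[, state_samples(design, ref), drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stop("both groups need >= 2 replicates")
  va <- row_sds(a)^2
  vb <- row_sds(b)^2
  if (any(vb == 0)) {
    stop("zero reference variance for gene(s): ",
         paste(utils::head(rownames(x)[vb == 0], 5), collapse = ", "),
         " (filter upstream)")
  }
  f <- va / vb
  df1 <- ncol(a) - 1
  df2 <- ncol(b) - 1
  lower <- stats::pf(f, df1, df2)
  p <- pmin(1, 2 * pmin(lower, 1 - lower))
  data.frame(gene = rownames(x), f = f, df1 = df1, df2 = df2, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validating wrapper around
#' [stats::p.adjust()] (an independent step-up oracle backs it in the tests).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential expression and differential variance analysis
#'
#' Runs per-state Welch t-tests and variance F-tests of every post-reference
#' state against the reference, adjusts p-values by Benjamini-Hochberg within
#' each state's family, and applies the call rules: a gene is differentially
#' expressed (DE) when, at some state, the adjusted t-test p-value is below
#' `alpha` AND its absolute log2 fold change exceeds the global fold-change
#' threshold (mean + `fc_k` * SD of all |log_fc| values pooled across genes
#' and states); a gene is differentially variable (DV) when its adjusted
#' F-test p-value is below `alpha` at some state.
#'
#' @param x expression matrix (log2 scale; fold change = difference of group
#'   means).
#' @param design a [sample_design()].
#' @param alpha significance level for adjusted p-values; default 0.05
#'   (strict <).
#' @param fc_k SD multiplier of the fold-change threshold; default 2.
#' @return list with `table` (gene x state records: `log_fc`, `t`, `df_t`,
#'   `p_t`, `q_t`, `f`, `p_f`, `q_f`), `fc_threshold`, `de_genes`, `dv_genes`.
#' @export
diff_expression <- function(x, design, alpha = 0.05, fc_k = 2) {
  check_matrix_design(x, design)
  post <- setdiff(design_states(design), reference_state(design))
  recs <- lapply(post, function(s) {
    w <- welch_t(x, design, s)
    f <- f_test_variance(x, design, s)
    data.frame(gene = w$gene, state = s, log_fc = w$log_fc,
               t = w$t, df_t = w$df, p_t = w$p, q_t = bh_adjust(w$p),
               f = f$f, p_f = f$p, q_f = bh_adjust(f$p),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  tab <- do.call(rbind, recs)
  fc_threshold <- mean(abs(tab$log_fc)) + fc_k * stats::sd(abs(tab$log_fc))
  de_by_state <- tab$q_t < alpha & abs(tab$log_fc) > fc_threshold
  dv_by_state <- tab$q_f < alpha
  de_genes <- sort(unique(tab$gene[de_by_state]))
  dv_genes <- sort(unique(tab$gene[dv_by_state]))
  message("diff_expression: |log_fc| threshold ", signif(fc_threshold, 4),
          "; ", length(de_genes), " DE and ", length(dv_genes),
          " DV gene(s) of ", nrow(x))
  list(table = tab, fc_threshold = fc_threshold,
       de_genes = de_genes, dv_genes = dv_genes)
}

#' DE call from a differential-analysis result
#' @param result a [diff_expression()] result.
#' @return character vector of DE gene ids.
#' @export
call_de <- function(result) result$de_genes

#' DV call from a differential-analysis result
#' @param result a [diff_expression()] result.
#' @return character vector of differentially variable gene ids.
#' @export
call_dv <- function(result) result$dv_genes
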