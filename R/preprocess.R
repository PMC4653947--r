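#' Log2-transform an expression matrix
#'
#' @param x raw intensity matrix.
#' @param offset non-negative pseudo-value added before the log; default 0.
#' @return elementwise `log2(x + offset)`.
#' @export
log2_transform <- function(x, offset = 0) {
  if (offset < 0) stop("offset must be >= 0")
  if (any(x + offset <= 0)) {
    bad <- which(x + offset <= 0, arr.ind = TRUE)[1, ]
    stop("value error: nonpositive value (after offset) at gene '",
         rownames(x)[bad[1]], "', sample '", colnames(x)[bad[2]], "'")
  }
  log2(x + offset)
}

#' Quantile-normalize samples
#'
#' Forces every sample (column) onto a common reference distribution: the
#' across-sample mean of sorted values. Tied values within a column receive the
#' mean of the reference values over their tied ranks.
#'
#' @param x numeric matrix (genes x samples), no missing values, >= 2 samples.
#' @return normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
  if (anyNA(x)) stop("missing values: impute upstream or fail")
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    ord <- order(col)
    ranks <- integer(length(col))
    ranks[ord] <- seq_along(col)
    newv <- ref[ranks]
    # ties: mean of reference values over the tied rank range
    if (anyDuplicated(col)) {
      tied <- stats::ave(ref[ranks], match(col, col), FUN = mean)
      newv <- tied
    }
    out[, j] <- newv
  }
  out
}

#' Filter genes on presence calls and per-state variance
#'
#' Keeps genes that (a) have a fraction of Present calls strictly above
#' `presence_frac` in every state (skipped when `calls` is NULL) and (b) have
#' sample SD > 0 across the replicates of every state.
#'
#' @param x expression matrix.
#' @param design a [sample_design()].
#' @param calls optional "P"/"A" character matrix aligned with `x`.
#' @param presence_frac presence-fraction cutoff (strict >); default 0.5.
#' @return the retained submatrix; removal counts are reported via `message()`.
#' @export
filter_genes <- function(x, design, calls = NULL, presence_frac = 0.5) {
  check_matrix_design(x, design)
  if (!is.null(calls)) {
    if (!identical(dim(calls), dim(x)) ||
        !identical(dimnames(calls), dimnames(x))) {
      stop("call matrix is not aligned with the expression matrix")
    }
  }
  states <- design_states(design)
  keep_presence <- rep(TRUE, nrow(x))
  keep_var <- rep(TRUE, nrow(x))
  for (s in states) {
    cols <- state_samples(design, s)
    if (!is.null(calls)) {
      frac_p <- rowMeans(calls[, cols, drop = FALSE] == "P")
      keep_presence <- keep_presence & (frac_p > presence_frac)
    }
    sds <- row_sds(x[, cols, drop = FALSE])
    keep_var <- keep_var & (sds > 0)
  }
  message("filter_genes: ", sum(!keep_presence), " gene(s) failed presence > ",
          presence_frac, "; ", sum(!keep_var),
          " gene(s) failed per-state SD > 0; retaining ",
          sum(keep_presence & keep_var), " of ", nrow(x))
  x[keep_presence & keep_var, , drop = FALSE]
}

#' Standardize each gene to Z-scores
#'
#' Each gene row is centred and scaled to mean 0 and sample SD 1 across all
#' samples jointly. Between-state SD differences are preserved (standardizing
#' within each state separately would force SD = 1 at every state and erase the
#' differential-variance signal); the transition score is invariant to any
#' per-gene affine rescaling, so this convention cannot change DVC calls.
#'
#' @param x expression matrix; every row must have SD > 0.
#' @return standardized matrix.
#' @export
zscore_genes <- function(x) {
  sds <- row_sds(x)
  if (any(sds == 0)) {
    stop("zero-SD row(s): ",
         paste(utils::head(rownames(x)[sds == 0], 5), collapse = ", "))
  }
  (x - rowMeans(x)) / sds
}

# internal: per-row sample SD (n-1 denominator)
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2) stop("need >= 2 columns for a sample SD")
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}
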