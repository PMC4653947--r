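#' Construct a sample design
#'
#' A sample design maps each sample to an ordered cellular state (e.g. a day of
#' a differentiation time course) and a replicate index. One state is the
#' reference (the undifferentiated state); all differential statistics compare
#' later states against it.
#'
#' @param samples character vector of unique sample identifiers.
#' @param states character vector, same length, the state of each sample.
#' @param replicates optional integer vector of replicate indices; defaults to
#'   1..n within each state in input order.
#' @param state_order ordered character vector of state labels; defaults to the
#'   order of first appearance in `states`.
#' @param reference the reference state; defaults to the first state of
#'   `state_order` (time courses are entered in order).
#' @return a `sample_design` data frame with columns `sample`, `state`,
#'   `replicate` and attributes `state_order` and `reference`.
#' @export
sample_design <- function(samples, states, replicates = NULL,
                          state_order = NULL, reference = NULL) {
  samples <- as.character(samples)
  states <- as.character(states)
  if (length(samples) != length(states)) {
    stop("samples and states must have equal length")
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifiers in design")
  }
  if (is.null(state_order)) state_order <- unique(states)
  if (!all(states %in% state_order)) {
    stop("every sample must map to a state in state_order")
  }
  if (is.null(reference)) reference <- state_order[1]
  if (!reference %in% state_order) {
    stop("reference state '", reference, "' not in state_order")
  }
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(samples), states, FUN = seq_along)
  }
  counts <- table(states)
  if (any(counts < 2)) {
    stop("every state needs >= 2 samples; offending state(s): ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  d <- data.frame(sample = samples, state = states,
                  replicate = as.integer(replicates),
                  stringsAsFactors = FALSE)
  attr(d, "state_order") <- state_order
  attr(d, "reference") <- reference
  class(d) <- c("sample_design", "data.frame")
  d
}

#' @export
print.sample_design <- function(x, ...) {
  cat("sample_design:", nrow(x), "samples,",
      length(attr(x, "state_order")), "states (reference:",
      attr(x, "reference"), ")\n")
  NextMethod()
  invisible(x)
}

#' Reference state of a design
#' @param design a `sample_design`.
#' @return the reference state label.
#' @export
reference_state <- function(design) attr(design, "reference")

#' Ordered state labels of a design
#' @param design a `sample_design`.
#' @return character vector of states in analysis order.
#' @export
design_states <- function(design) attr(design, "state_order")

#' Samples belonging to one state
#' @param design a `sample_design`.
#' @param state a state label.
#' @return character vector of sample ids.
#' @export
state_samples <- function(design, state) {
  if (!state %in% design_states(design)) stop("unknown state: ", state)
  design$sample[design$state == state]
}

# internal: check matrix/design agreement
check_matrix_design <- function(x, design) {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must carry gene (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers")
  miss_sheet <- setdiff(colnames(x), design$sample)
  if (length(miss_sheet)) {
    stop("samples present in matrix but absent from design: ",
         paste(miss_sheet, collapse = ", "))
  }
  miss_mat <- setdiff(design$sample, colnames(x))
  if (length(miss_mat)) {
    stop("design rows absent from matrix: ", paste(miss_mat, collapse = ", "))
  }
  invisible(TRUE)
}
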