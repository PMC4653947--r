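#' Correlation distance between genes
#'
#' Pairwise distance d(i, j) = 1 - PCC(i, j) between gene rows, computed over
#' the supplied samples (typically the reference-state replicates). With the
#' `unsigned` option the distance is 1 - |PCC|, which places anti-correlated
#' genes together; the signed form is the default and keeps them apart.
#'
#' @param x genes x samples matrix restricted to the samples of one state;
#'   needs >= 3 samples and per-row SD > 0 within them.
#' @param unsigned use 1 - |PCC| instead of 1 - PCC.
#' @return symmetric distance matrix, zero diagonal, range \[0, 2\]
#'   (\[0, 1\] unsigned).
#' @export
correlation_distance <- function(x, unsigned = FALSE) {
  if (ncol(x) < 3) stop("need >= 3 samples for correlation distances")
  sds <- row_sds(x)
  if (any(sds == 0)) {
    stop("zero-SD gene(s) within these samples: ",
         paste(utils::head(rownames(x)[sds == 0], 5), collapse = ", "))
  }
  r <- stats::cor(t(x))
  d <- if (unsigned) 1 - abs(r) else 1 - r
  diag(d) <- 0
  # clamp tiny negative values from floating-point round-off
  d[d < 0] <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Inter-cluster distance is the arithmetic mean of all cross-pair distances.
#' Implemented via [stats::hclust()]; an independent naive implementation
#' backs it in the test suite.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @return an `hclust` object.
#' @export
average_linkage <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-12)) {
      stop("distance matrix must be symmetric")
    }
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "average")
}

#' Hybrid dynamic tree cut
#'
#' Detects co-expression modules from an average-linkage dendrogram in two
#' stages, following the hybrid dynamic tree-cut scheme: (1) bottom-up,
#' shape-based branch identification — a branch becomes a module when, at the
#' merge where it is absorbed into the rest of the tree, it has at least
#' `min_size` leaves, a core gap (absorption height minus the height at which
#' its core, the earliest `min_size` members, was complete) of at least the
#' gap threshold, and a core scatter (mean height of its earliest
#' `min_size - 1` internal merges) below the scatter ceiling; (2)
#' distance-based assignment of stray leaves — an unassigned leaf joins the
#' module with the smallest average distance, provided it lies at most 50%
#' farther from the module than the module's own most peripheral member
#' (its average distance to the rest). Measuring gap and
#' scatter on the branch core makes detection robust to stray leaves that
#' attach to a branch above its core, which with few replicates happens
#' continuously by chance correlation.
#'
#' Every lock additionally requires the core to be intrinsically tight: core
#' scatter at most `tight_scatter` in absolute correlation-distance units
#' (mean core correlation >= 0.6 at the default). Branches only severed by the
#' cut height (including an undivided root) are locked on size and tightness
#' alone, since no gap can be demonstrated for them; this keeps a continuum of
#' noise merges from being declared a module while still recognising a
#' genuinely coherent undivided tree.
#'
#' The gap and scatter thresholds are fractions of the height band between the
#' 5th percentile of merge heights and `cut_height`, parameterised by
#' `deep_split` (0-4) exactly as in the published hybrid algorithm:
#' `max_core_scatter` fraction 0.64/0.73/0.82/0.91/0.95 and `min_gap` fraction
#' `(1 - scatter_fraction) * 3/4`.
#'
#' @param dendro an `hclust` object from [average_linkage()].
#' @param d the distance matrix the dendrogram was built from (used by the
#'   assignment stage).
#' @param min_size minimal module size; default 100.
#' @param deep_split split sensitivity, integer 0-4; default 1.
#' @param cut_height maximum merge height considered; default 0.99 * max
#'   height.
#' @param tight_scatter absolute core-scatter ceiling for gap-less branches;
#'   default 0.4.
#' @param pam_stage run the stray-leaf assignment stage; default TRUE.
#' @return named integer vector of module labels (0 = unassigned), labels
#'   1..k in decreasing module size; attributes `n_modules` and `params`.
#' @export
cutree_dynamic <- function(dendro, d, min_size = 100, deep_split = 1,
                           cut_height = NULL, tight_scatter = 0.4,
                           pam_stage = TRUE) {
  stopifnot(inherits(dendro, "hclust"))
  if (min_size < 2) stop("config error: min_size must be >= 2")
  if (!deep_split %in% 0:4) stop("config error: deep_split must be 0..4")
  n <- length(dendro$order)
  if (n < min_size) stop("dendrogram has fewer leaves than min_size")
  labels_in <- if (is.null(dendro$labels)) as.character(seq_len(n)) else dendro$labels
  if (is.matrix(d)) dm <- d else dm <- as.matrix(d)
  h <- dendro$height
  mg <- dendro$merge
  if (is.null(cut_height)) cut_height <- 0.99 * max(h)
  ref_height <- stats::quantile(h, 0.05, names = FALSE)
  scatter_frac <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  gap_frac <- (1 - scatter_frac) * 3 / 4
  max_scatter <- ref_height + scatter_frac * (cut_height - ref_height)
  # absolute floor: splits below 0.01 correlation-distance units are noise
  min_gap <- max(gap_frac * (cut_height - ref_height), 0.01)

  members <- vector("list", n - 1)   # leaf indices of ordinary branches
  core_h <- vector("list", n - 1)    # earliest internal merge heights (capped)
  top_h <- numeric(n - 1)            # height of last internal merge
  composite <- logical(n - 1)        # node already resolved into clusters
  clusters <- list()
  floating <- integer(0)

  side_info <- function(s) {
    if (s < 0) {
      list(members = -s, core = numeric(0), top = -Inf, composite = FALSE)
    } else {
      list(members = members[[s]], core = core_h[[s]], top = top_h[s],
           composite = composite[s])
    }
  }
  core_scatter <- function(info) {
    k <- min(length(info$members), min_size) - 1
    if (k < 1) return(0)
    mean(info$core[seq_len(min(k, length(info$core)))])
  }
  # height at which the branch core (first min_size members) was complete;
  # stray leaves attaching above the core do not move it, so the gap criterion
  # measures the separation between the core and the branch's absorption point
  core_top <- function(info) {
    if (!length(info$core)) return(info$top)
    k <- min(length(info$members), min_size) - 1
    info$core[min(k, length(info$core))]
  }
  worthy <- function(info, at) {
    length(info$members) >= min_size &&
      (at - core_top(info)) >= min_gap &&
      core_scatter(info) <= min(max_scatter, tight_scatter)
  }
  # a branch with no demonstrated gap (severed at the cut, or the root)
  severed_ok <- function(info) {
    length(info$members) >= min_size &&
      core_scatter(info) <= min(max_scatter, tight_scatter)
  }
  finalize <- function(info) {
    if (info$composite) return()
    if (severed_ok(info)) {
      clusters[[length(clusters) + 1]] <<- info$members
    } else {
      floating <<- c(floating, info$members)
    }
  }

  for (i in seq_len(n - 1)) {
    a <- side_info(mg[i, 1])
    b <- side_info(mg[i, 2])
    at <- h[i]
    if (at > cut_height) {
      finalize(a)
      finalize(b)
      composite[i] <- TRUE
      next
    }
    if (!a$composite && !b$composite) {
      wa <- worthy(a, at)
      wb <- worthy(b, at)
      if (wa && wb) {
        clusters <- c(clusters, list(a$members), list(b$members))
        composite[i] <- TRUE
      } else if (wa || wb) {
        keep <- if (wa) a else b
        drop <- if (wa) b else a
        clusters[[length(clusters) + 1]] <- keep$members
        floating <- c(floating, drop$members)
        composite[i] <- TRUE
      } else {
        members[[i]] <- c(a$members, b$members)
        ch <- sort(c(a$core, b$core, at))
        if (length(ch) > min_size) ch <- ch[seq_len(min_size)]
        core_h[[i]] <- ch
        top_h[i] <- at
      }
    } else {
      for (s in list(a, b)) {
        if (s$composite) next
        if (worthy(s, at)) {
          clusters[[length(clusters) + 1]] <- s$members
        } else {
          floating <- c(floating, s$members)
        }
      }
      composite[i] <- TRUE
    }
  }
  root <- n - 1
  if (!composite[root]) finalize(side_info(root))

  # stage 2: assign stray leaves to sufficiently close modules
  if (pam_stage && length(clusters) && length(floating)) {
    radii <- vapply(clusters, function(cl) {
      if (length(cl) < 2) return(0)
      max(vapply(cl, function(g) mean(dm[g, setdiff(cl, g)]), numeric(1)))
    }, numeric(1))
    avg_d <- vapply(clusters, function(cl) {
      rowMeans(dm[floating, cl, drop = FALSE])
    }, numeric(length(floating)))
    avg_d <- matrix(avg_d, nrow = length(floating))
    best <- max.col(-avg_d, ties.method = "first")
    best_d <- avg_d[cbind(seq_along(floating), best)]
    take <- best_d <= 1.5 * radii[best]
    for (ci in seq_along(clusters)) {
      clusters[[ci]] <- c(clusters[[ci]], floating[take & best == ci])
    }
    floating <- floating[!take]
  }

  labels <- integer(n)
  if (length(clusters)) {
    sizes <- lengths(clusters)
    ord <- order(-sizes, vapply(clusters, min, numeric(1)))
    for (rank in seq_along(ord)) labels[clusters[[ord[rank]]]] <- rank
  }
  names(labels) <- labels_in
  structure(labels, n_modules = sum(lengths(clusters) > 0),
            params = list(min_size = min_size, deep_split = deep_split,
                          cut_height = cut_height,
                          tight_scatter = tight_scatter,
                          pam_stage = pam_stage))
}

#' Detect co-expression modules at the reference state
#'
#' Convenience wrapper: restricts the matrix to the reference-state samples,
#' builds 1 - PCC distances, clusters by average linkage, and applies the
#' hybrid dynamic tree cut.
#'
#' @param x expression matrix (genes x samples).
#' @param design a [sample_design()].
#' @param min_size,deep_split,cut_height,tight_scatter,pam_stage passed to
#'   [cutree_dynamic()].
#' @param unsigned passed to [correlation_distance()].
#' @return module label vector as from [cutree_dynamic()].
#' @export
detect_modules <- function(x, design, min_size = 100, deep_split = 1,
                           cut_height = NULL, tight_scatter = 0.4,
                           pam_stage = TRUE, unsigned = FALSE) {
  check_matrix_design(x, design)
  ref_cols <- state_samples(design, reference_state(design))
  d <- correlation_distance(x[, ref_cols, drop = FALSE], unsigned = unsigned)
  dendro <- average_linkage(d)
  labels <- cutree_dynamic(dendro, d, min_size = min_size,
                           deep_split = deep_split, cut_height = cut_height,
                           tight_scatter = tight_scatter,
                           pam_stage = pam_stage)
  message("detect_modules: ", attr(labels, "n_modules"), " module(s); ",
          sum(labels == 0), " of ", length(labels), " genes unassigned")
  labels
}
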