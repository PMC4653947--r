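#' Upper-tail cumulative hypergeometric probability
#'
#' Exact over-representation probability P(X >= k) for a hypergeometric draw:
#' a universe of `N` genes of which `K` are annotated, a query of size `n`,
#' and an observed overlap of `k`. Computed via [stats::phyper()] (the
#' enumeration oracle in the tests verifies it to 1e-12).
#'
#' @param N universe size.
#' @param K annotated genes in the universe.
#' @param n query size.
#' @param k observed overlap.
#' @return P(X >= k); 1 when k = 0.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n) || k < 0) stop("k must lie in [0, min(K, n)]")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of gene sets in a query list
#'
#' @param query character vector of query gene ids (must lie in `universe`).
#' @param collection named list of gene sets (e.g. from [read_gmt()]); members
#'   outside the universe are dropped (count reported via `message()`).
#' @param universe character vector of background gene ids.
#' @param bh also report BH-adjusted p-values; default FALSE (raw enrichment
#'   p-values are reported by default).
#' @return data frame, one row per set, sorted by ascending p: `set`,
#'   `universe_size`, `annotated`, `query_size`, `overlap`, `p` (and `q` with
#'   `bh = TRUE`), `members` (overlapping ids, comma-separated).
#' @export
enrich <- function(query, collection, universe, bh = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  }
  rows <- lapply(names(collection), function(nm) {
    members <- unique(as.character(collection[[nm]]))
    dropped <- sum(!members %in% universe)
    if (dropped) {
      message("enrich: set '", nm, "': ", dropped,
              " member(s) outside the universe dropped")
    }
    members <- intersect(members, universe)
    hits <- intersect(query, members)
    data.frame(set = nm, universe_size = length(universe),
               annotated = length(members), query_size = length(query),
               overlap = length(hits),
               p = hypergeom_upper_tail(length(universe), length(members),
                                        length(query), length(hits)),
               members = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  if (bh) res$q <- bh_adjust(res$p)
  res
}

#' Per-module enrichment of a gene flag
#'
#' Tests each module for over-representation of flagged genes (for example
#' variance-decreased genes) against the universe of all clustered genes.
#'
#' @param flags named logical vector over genes.
#' @param modules named integer module labels (0 = unassigned; excluded from
#'   testing but label-0 genes are not part of the universe either).
#' @return data frame as from [enrich()], one row per nonzero module, set
#'   names `module_<label>`.
#' @export
module_enrichment <- function(flags, modules) {
  genes <- names(modules)[modules != 0]
  if (!all(genes %in% names(flags))) {
    stop("flags must be defined for every module gene")
  }
  collection <- lapply(split(genes, modules[genes]), identity)
  names(collection) <- paste0("module_", names(collection))
  enrich(query = genes[flags[genes]], collection = collection,
         universe = genes)
}

#' Cross-species overlap test through an ortholog map
#'
#' Maps a species-B gene set into species-A space (a species-A gene is a hit
#' when any of its mapped partners is in the B set — the permissive
#' many-to-many rule), intersects the two universes after mapping, and applies
#' the upper-tail hypergeometric test to the overlap.
#'
#' @param set_a species-A gene set.
#' @param set_b species-B gene set.
#' @param map data frame with columns `a`, `b` (as from
#'   [read_ortholog_map()]).
#' @param universe_a species-A universe.
#' @param universe_b species-B universe.
#' @return one-row data frame: `universe_size`, `annotated` (mapped B set in
#'   universe), `query_size` (A set in universe), `overlap`, `p`, `members`.
#' @export
ortholog_overlap_test <- function(set_a, set_b, map, universe_a, universe_b) {
  if (!nrow(map)) stop("empty ortholog map")
  unmapped <- sum(!unique(set_b) %in% map$b)
  if (unmapped) {
    message("ortholog_overlap_test: ", unmapped,
            " species-B gene(s) absent from the map excluded")
  }
  mapped_universe_b <- unique(map$a[map$b %in% universe_b])
  universe <- intersect(unique(universe_a), mapped_universe_b)
  if (!length(universe)) stop("empty post-mapping universe")
  mapped_b <- unique(map$a[map$b %in% set_b])
  K_set <- intersect(mapped_b, universe)
  n_set <- intersect(unique(set_a), universe)
  hits <- intersect(K_set, n_set)
  data.frame(universe_size = length(universe), annotated = length(K_set),
             query_size = length(n_set), overlap = length(hits),
             p = hypergeom_upper_tail(length(universe), length(K_set),
                                      length(n_set), length(hits)),
             members = paste(sort(hits), collapse = ","),
             stringsAsFactors = FALSE)
}
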