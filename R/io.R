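#' Read an expression matrix and its sample sheet
#'
#' The expression file is TSV: first column gene id (header `gene` or
#' anything), remaining columns one per sample. The sample sheet is TSV with
#' columns `sample`, `state`, `replicate`, optionally preceded by a line
#' `#reference=<state>` naming the reference state; without it the first state
#' in order of appearance is the reference.
#'
#' @param path expression TSV path.
#' @param sample_sheet_path sample sheet TSV path.
#' @return list with elements `matrix` (genes x samples numeric matrix) and
#'   `design` (a [sample_design()]).
#' @export
read_expression <- function(path, sample_sheet_path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    stop("format error: duplicate sample id in expression header")
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "")
  if (anyDuplicated(rownames(tab))) {
    stop("format error: duplicate gene id in expression file")
  }
  x <- suppressWarnings(matrix(as.numeric(as.matrix(tab)), nrow = nrow(tab),
                               dimnames = dimnames(tab)))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop("format error: non-numeric value at gene '", rownames(tab)[bad[1]],
         "', sample '", colnames(tab)[bad[2]], "'")
  }
  design <- read_sample_sheet(sample_sheet_path)
  check_matrix_design(x, design)
  x <- x[, design$sample, drop = FALSE]
  list(matrix = x, design = design)
}

#' Read a sample sheet
#' @param path TSV with columns sample, state, replicate; optional leading
#'   `#reference=<state>` line.
#' @return a [sample_design()].
#' @export
read_sample_sheet <- function(path) {
  lines <- readLines(path)
  reference <- NULL
  if (length(lines) && startsWith(lines[1], "#reference=")) {
    reference <- sub("^#reference=", "", lines[1])
    lines <- lines[-1]
  }
  tab <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  need <- c("sample", "state", "replicate")
  if (!all(need %in% colnames(tab))) {
    stop("format error: sample sheet needs columns ",
         paste(need, collapse = ", "))
  }
  sample_design(tab$sample, tab$state,
                replicates = as.integer(tab$replicate),
                reference = reference)
}

#' Write an expression matrix as TSV
#' @param x genes x samples numeric matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x),
                   format_num(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample sheet as TSV
#' @param design a [sample_design()].
#' @param path output path.
#' @export
write_sample_sheet <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#reference=", reference_state(design)), con)
  utils::write.table(as.data.frame(design)[, c("sample", "state", "replicate")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: deterministic, full-precision numeric formatting for TSV output
format_num <- function(x) {
  out <- apply(x, 2, function(col) sprintf("%.15g", col))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(x))
  dimnames(out) <- dimnames(x)
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Duplicate members within a line are dropped with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("format error: GMT line ", i, " has fewer than 3 fields")
    }
    name <- fields[1]
    if (name %in% names(sets)) stop("format error: duplicate set name '", name, "'")
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT set '", name, "': ",
              sum(duplicated(members)), " duplicate member(s) dropped")
      members <- unique(members)
    }
    attr(members, "description") <- fields[2]
    sets[[name]] <- members
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors (optional `description`
#'   attributes; empty string if absent).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- ""
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ortholog map
#'
#' @param path TSV with two columns (species A gene, species B gene); a header
#'   row is expected. Mapping may be many-to-many; duplicate pairs are dropped.
#' @return data frame with columns `a` and `b`.
#' @export
read_ortholog_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("format error: ortholog map needs two columns")
  map <- data.frame(a = tab[[1]], b = tab[[2]], stringsAsFactors = FALSE)
  unique(map)
}

#' Write a co-expression network edge list
#'
#' Pairs are canonicalised (source < target in C-locale order), deduplicated,
#' and written in lexicographic order by source then target, so output is
#' byte-deterministic.
#'
#' @param edges data frame with columns `source`, `target`, `pcc`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  if (nrow(edges)) {
    if (any(edges$source == edges$target)) {
      stop("consistency error: self-edge in edge list")
    }
    swap <- edges$source > edges$target
    tmp <- edges$source[swap]
    edges$source[swap] <- edges$target[swap]
    edges$target[swap] <- tmp
    edges <- edges[!duplicated(edges[, c("source", "target")]), , drop = FALSE]
    edges <- edges[order(edges$source, edges$target, method = "radix"), ,
                   drop = FALSE]
    edges$pcc <- sprintf("%.15g", edges$pcc)
  }
  utils::write.table(edges[, c("source", "target", "pcc"), drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge list
#' @param path TSV with columns source, target, pcc.
#' @return data frame with those columns.
#' @export
read_edge_list <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "numeric"),
                    quote = "")
}

# internal: write a generic results table deterministically
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
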