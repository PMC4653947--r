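# Independent brute-force oracles. These deliberately share no code with the
# package implementations they verify.

# O(n^3) UPGMA: returns the cophenetic distance matrix (merge memberships and
# heights jointly), which is invariant to tie-break conventions when all
# pairwise averages are distinct.
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1]]]
    b <- clusters[[best[2]]]
    coph[a, b] <- best_h
    coph[b, a] <- best_h
    clusters[[best[1]]] <- c(a, b)
    clusters <- clusters[-best[2]]
  }
  coph
}

# rank-mean quantile normalization by explicit tie-group bookkeeping
oracle_quantile_normalize <- function(x) {
  sorted_cols <- apply(x, 2, sort)
  ref <- rowMeans(sorted_cols)
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    ord <- order(col)
    assigned <- numeric(length(col))
    pos <- 1
    while (pos <= length(col)) {
      run <- pos
      while (run < length(col) && col[ord[run + 1]] == col[ord[pos]]) {
        run <- run + 1
      }
      assigned[ord[pos:run]] <- mean(ref[pos:run])
      pos <- run + 1
    }
    out[, j] <- assigned
  }
  out
}

# literal step-up BH definition: q_(i) = min over j >= i of min(1, m p_(j) / j)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q[ord[i]] <- min(1, cand)
  }
  q
}

# log-space enumeration of the hypergeometric upper tail
oracle_hyper_upper <- function(N, K, n, k) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  logs <- lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)
  mx <- max(logs)
  exp(mx + log(sum(exp(logs - mx))))
}

# all-pairs per-state statistics with scalar loops
oracle_state_stats <- function(x, design, modules, epsilon = 1e-6) {
  states <- design_states(design)
  genes <- rownames(x)
  scored <- genes[modules[genes] != 0]
  rows <- list()
  for (s in states) {
    cols <- state_samples(design, s)
    for (g in scored) {
      partners_in <- setdiff(genes[modules[genes] == modules[g]], g)
      partners_out <- genes[modules[genes] != modules[g]]
      mpcc <- mean(vapply(partners_in, function(p) {
        abs(stats::cor(x[g, cols], x[p, cols]))
      }, numeric(1)))
      opcc <- if (length(partners_out)) {
        mean(vapply(partners_out, function(p) {
          abs(stats::cor(x[g, cols], x[p, cols]))
        }, numeric(1)))
      } else 0
      sdv <- stats::sd(x[g, cols])
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, state = s, sd = sdv, mpcc = mpcc, opcc = opcc,
        index = mpcc * sdv / max(opcc, epsilon), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
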