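#' Configuration for the synthetic transition-course generator
#'
#' The generator plants co-expression modules driven by one latent factor per
#' module. A module's factor has standard deviation `factor_sd[s]` at state s;
#' a *transition* module has a large factor SD at the reference state that
#' collapses afterwards, which jointly produces high within-module correlation
#' and high per-gene SD at the reference state only (within-module correlation
#' approx lambda^2 tau^2 / (lambda^2 tau^2 + sigma^2), per-gene SD approx
#' sqrt(lambda^2 tau^2 + sigma^2)). Background genes have no factor loading.
#' Differentially expressed genes are drawn from the background and receive a
#' mean shift from `de_onset` onwards, with unchanged variance and correlation.
#'
#' The defaults are the package's reference study conditions: two transition
#' modules (size 120, factor SD 2.0 at reference then 0.2), one stable module
#' (size 120, factor SD 1.0 throughout), 800 background genes, 40 DE genes
#' with effect size 2.0, 4 states x 8 replicates, noise SD 0.5, seed 17.
#'
#' @param n_states number of ordered states (state 1 is the reference).
#' @param n_reps replicates per state.
#' @param modules list of module specs, each a list with `size`,
#'   `loading_range` (c(lo, hi) for per-gene loadings lambda), and `factor_sd`
#'   (length `n_states`, tau_s >= 0).
#' @param n_background number of independent background genes.
#' @param noise_sd residual noise SD sigma (> 0).
#' @param baseline_range range of per-gene baseline means (log2 intensity
#'   scale).
#' @param n_de number of planted DE genes (drawn from the background).
#' @param de_effect mean shift delta added from `de_onset` onwards.
#' @param de_onset index (in state order) of the first state showing the DE
#'   shift; must be > 1 (a non-reference state).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_states = 4, n_reps = 8,
                       modules = list(
                         list(size = 120, loading_range = c(0.8, 1.2),
                              factor_sd = c(2.0, rep(0.2, n_states - 1))),
                         list(size = 120, loading_range = c(0.8, 1.2),
                              factor_sd = c(2.0, rep(0.2, n_states - 1))),
                         list(size = 120, loading_range = c(0.8, 1.2),
                              factor_sd = rep(1.0, n_states))),
                       n_background = 800, noise_sd = 0.5,
                       baseline_range = c(6, 12),
                       n_de = 40, de_effect = 2.0, de_onset = 2,
                       seed = 17) {
  if (n_reps < 1) stop("config error: zero replicates")
  if (n_states < 2) stop("config error: need >= 2 states")
  if (noise_sd <= 0) stop("config error: noise_sd must be > 0")
  if (n_background < 0 || n_de < 0) stop("config error: negative count")
  if (n_de > n_background) stop("config error: n_de exceeds n_background")
  if (de_onset < 2 || de_onset > n_states) {
    stop("config error: de_onset must be a non-reference state index")
  }
  for (m in modules) {
    if (m$size < 0) stop("config error: negative module size")
    if (length(m$factor_sd) != n_states || any(m$factor_sd < 0)) {
      stop("config error: factor_sd must be length n_states, all >= 0")
    }
  }
  structure(list(n_states = n_states, n_reps = n_reps, modules = modules,
                 n_background = n_background, noise_sd = noise_sd,
                 baseline_range = baseline_range, n_de = n_de,
                 de_effect = de_effect, de_onset = de_onset, seed = seed),
            class = "sim_config")
}

#' Generate a synthetic replicated expression time course
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (genes x samples, log2 scale), `design`
#'   (a [sample_design()]), and `truth`: a list with `module_of_gene`
#'   (named integer vector, 0 = background), `transition_genes` (genes of
#'   modules whose factor SD differs between the reference and some later
#'   state), `de_genes`, and the `config`. Deterministic given `config$seed`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_mod_genes <- sum(vapply(config$modules, `[[`, numeric(1), "size"))
  n_genes <- n_mod_genes + config$n_background
  genes <- sprintf("gene%04d", seq_len(n_genes))
  states <- paste0("S", seq_len(config$n_states) - 1)
  samples <- as.vector(t(outer(states, seq_len(config$n_reps),
                               function(s, r) paste0(s, "_r", r))))
  design <- sample_design(samples,
                          rep(states, each = config$n_reps),
                          state_order = states, reference = states[1])

  module_of_gene <- integer(n_genes)
  names(module_of_gene) <- genes
  x <- matrix(0, n_genes, length(samples), dimnames = list(genes, samples))
  x[] <- stats::rnorm(length(x), sd = config$noise_sd)
  mu <- stats::runif(n_genes, config$baseline_range[1], config$baseline_range[2])
  x <- x + mu

  offset <- 0L
  for (mi in seq_along(config$modules)) {
    spec <- config$modules[[mi]]
    if (spec$size == 0) next
    idx <- offset + seq_len(spec$size)
    offset <- offset + spec$size
    module_of_gene[idx] <- mi
    lambda <- stats::runif(spec$size, spec$loading_range[1], spec$loading_range[2])
    for (si in seq_len(config$n_states)) {
      f <- stats::rnorm(config$n_reps, sd = spec$factor_sd[si])
      cols <- (si - 1) * config$n_reps + seq_len(config$n_reps)
      x[idx, cols] <- x[idx, cols] + outer(lambda, f)
    }
  }

  bg_idx <- which(module_of_gene == 0)
  de_idx <- if (config$n_de > 0) sample(bg_idx, config$n_de) else integer(0)
  if (length(de_idx)) {
    de_cols <- which(rep(seq_len(config$n_states), each = config$n_reps) >=
                       config$de_onset)
    x[de_idx, de_cols] <- x[de_idx, de_cols] + config$de_effect
  }

  is_transition <- vapply(config$modules, function(m) {
    m$size > 0 && any(m$factor_sd[-1] != m$factor_sd[1])
  }, logical(1))
  transition_genes <- genes[module_of_gene %in% which(is_transition)]

  list(matrix = x, design = design,
       truth = list(module_of_gene = module_of_gene,
                    transition_genes = transition_genes,
                    de_genes = genes[de_idx],
                    config = config))
}

#' Generate a synthetic Present/Absent detection-call matrix
#'
#' A proxy for microarray presence calls, used to exercise the presence-call
#' expression filter: each cell is independently Absent with probability
#' `absent_fraction`.
#'
#' @param x expression matrix whose dimensions and dimnames are mirrored.
#' @param absent_fraction probability of an "A" call, in \[0, 1\].
#' @param seed integer RNG seed.
#' @return character matrix of "P"/"A", same dimnames as `x`.
#' @export
simulate_presence_calls <- function(x, absent_fraction, seed = 1L) {
  if (absent_fraction < 0 || absent_fraction > 1) {
    stop("absent_fraction must be in [0, 1]")
  }
  set.seed(seed)
  calls <- matrix(ifelse(stats::runif(length(x)) < absent_fraction, "A", "P"),
                  nrow = nrow(x), dimnames = dimnames(x))
  calls
}

#' Write the synthetic ground truth as TSV
#' @param truth the `truth` element of [simulate_dataset()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  df <- data.frame(gene = names(truth$module_of_gene),
                   module = unname(truth$module_of_gene),
                   transition = as.integer(names(truth$module_of_gene) %in%
                                             truth$transition_genes),
                   de = as.integer(names(truth$module_of_gene) %in%
                                     truth$de_genes),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
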