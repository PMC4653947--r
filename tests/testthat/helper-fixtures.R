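# Small in-code fixtures shared across test files.

# deterministic toy matrix: g genes x (states * reps) samples of N(0, 1) noise
toy_matrix <- function(g = 10, states = 2, reps = 4, seed = 42) {
  set.seed(seed)
  st <- paste0("S", seq_len(states) - 1)
  samples <- as.vector(t(outer(st, seq_len(reps), paste, sep = "_r")))
  x <- matrix(rnorm(g * length(samples)), g,
              dimnames = list(sprintf("g%02d", seq_len(g)), samples))
  design <- sample_design(samples, rep(st, each = reps))
  list(x = x, design = design)
}

# two clean 5-gene modules over 2 states x 4 reps, for exact-statistics tests
toy_modular <- function(seed = 7) {
  set.seed(seed)
  st <- c("S0", "S1")
  samples <- as.vector(t(outer(st, 1:4, paste, sep = "_r")))
  x <- matrix(0, 10, 8, dimnames = list(sprintf("g%02d", 1:10), samples))
  for (s in 1:2) {
    cols <- (s - 1) * 4 + 1:4
    f1 <- rnorm(4)
    f2 <- rnorm(4)
    x[1:5, cols] <- outer(runif(5, 0.5, 1.5), f1) + matrix(rnorm(20, sd = 0.3), 5)
    x[6:10, cols] <- outer(runif(5, 0.5, 1.5), f2) + matrix(rnorm(20, sd = 0.3), 5)
  }
  modules <- setNames(rep(1:2, each = 5), rownames(x))
  design <- sample_design(samples, rep(st, each = 4))
  list(x = x, design = design, modules = modules)
}

# null study conditions: two stable modules, no transition, no DE genes;
# all states identically distributed
null_config <- function(seed) {
  sim_config(n_states = 4, n_reps = 8,
             modules = list(
               list(size = 100, loading_range = c(0.8, 1.2),
                    factor_sd = rep(1, 4)),
               list(size = 100, loading_range = c(0.8, 1.2),
                    factor_sd = rep(1, 4))),
             n_background = 300, n_de = 0, seed = seed)
}

# the 10-gene preprocessing filter fixture: known presence/variance violations
filter_fixture <- function() {
  st <- c("S0", "S1")
  samples <- as.vector(t(outer(st, 1:4, paste, sep = "_r")))
  design <- sample_design(samples, rep(st, each = 4))
  set.seed(3)
  x <- matrix(rnorm(80, mean = 8), 10,
              dimnames = list(sprintf("g%02d", 1:10), samples))
  calls <- matrix("P", 10, 8, dimnames = dimnames(x))
  # g01: constant across S0 replicates -> fails SD > 0
  x[1, 1:4] <- 5
  # g02: constant across S1 replicates -> fails SD > 0
  x[2, 5:8] <- 5
  # g03: presence exactly 2/4 = 0.5 in S0 -> fails strict > 0.5
  calls[3, 1:2] <- "A"
  # g04: presence 1/4 in S1 -> fails
  calls[4, 5:7] <- "A"
  # g05: presence 3/4 in both states -> passes
  calls[5, 1] <- "A"
  calls[5, 5] <- "A"
  list(x = x, design = design, calls = calls,
       expected_kept = sprintf("g%02d", 5:10))
}
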