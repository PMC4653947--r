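test_that("generation is deterministic given the seed", {
  a <- simulate_dataset(sim_config())
  b <- simulate_dataset(sim_config())
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth$de_genes, b$truth$de_genes)
  c <- simulate_dataset(sim_config(seed = 18))
  expect_false(identical(a$matrix, c$matrix))
})

test_that("factor collapse produces the variance-correlation coupling", {
  # one module (120 genes, lambda in [0.8, 1.2], tau = 2.0 then 0.2), sigma 0.5:
  # within-module correlation ~ l^2 t^2 / (l^2 t^2 + s^2) is high at the
  # reference and low afterwards
  cfg <- sim_config(n_states = 3, n_reps = 8,
                    modules = list(list(size = 120,
                                        loading_range = c(0.8, 1.2),
                                        factor_sd = c(2.0, 0.2, 0.2))),
                    n_background = 800, noise_sd = 0.5, n_de = 0, seed = 11)
  sim <- simulate_dataset(cfg)
  mod_genes <- names(sim$truth$module_of_gene)[sim$truth$module_of_gene == 1]
  mean_pcc <- function(state) {
    cols <- state_samples(sim$design, state)
    r <- cor(t(sim$matrix[mod_genes, cols]))
    mean(r[upper.tri(r)])
  }
  expect_gt(mean_pcc("S0"), mean_pcc("S2"))
  # closed-form population value at the reference is ~ 4 / 4.25 = 0.94 at
  # lambda = 1; the realized factor variance over 8 replicates is chi-square
  # distributed and shared by all pairs, so allow a wide sampling margin
  expect_gt(mean_pcc("S0"), 0.5)
  expect_lt(mean_pcc("S2"), 0.4)
})

test_that("constant factor SD gives no systematic between-state SD difference", {
  diffs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_states = 2, n_reps = 8,
                      modules = list(list(size = 60,
                                          loading_range = c(0.8, 1.2),
                                          factor_sd = c(1, 1))),
                      n_background = 0, n_de = 0, seed = s)
    sim <- simulate_dataset(cfg)
    s0 <- apply(sim$matrix[, state_samples(sim$design, "S0")], 1, sd)
    s1 <- apply(sim$matrix[, state_samples(sim$design, "S1")], 1, sd)
    mean(s0 - s1)
  }, numeric(1))
  # the shared module factor makes per-seed mean differences correlated across
  # genes, so test centering with a t-statistic over seeds rather than a
  # fixed absolute bound
  expect_lt(abs(mean(diffs)) / (sd(diffs) / sqrt(length(diffs))), 3)
})

test_that("planted transition genes have higher reference SD than background", {
  sim <- simulate_dataset(sim_config())
  cols <- state_samples(sim$design, "S0")
  sds <- apply(sim$matrix[, cols], 1, sd)
  tg <- sim$truth$transition_genes
  bg <- names(sim$truth$module_of_gene)[sim$truth$module_of_gene == 0]
  expect_gt(min(sds[tg]), max(sds[bg]) * 0.8)
  expect_gt(mean(sds[tg]), 2 * mean(sds[bg]))
})

test_that("DE genes come from the background and shift only after onset", {
  sim <- simulate_dataset(sim_config())
  expect_length(intersect(sim$truth$de_genes, sim$truth$transition_genes), 0)
  expect_true(all(sim$truth$module_of_gene[sim$truth$de_genes] == 0))
  de <- sim$truth$de_genes
  m0 <- rowMeans(sim$matrix[de, state_samples(sim$design, "S0")])
  m1 <- rowMeans(sim$matrix[de, state_samples(sim$design, "S1")])
  expect_gt(mean(m1 - m0), 1.5)
})

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_reps = 0), "zero replicates")
  expect_error(sim_config(de_onset = 1), "non-reference")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(modules = list(list(size = 10,
                                              loading_range = c(1, 1),
                                              factor_sd = c(1, 1)))),
               "factor_sd")
})

test_that("presence-call generation hits the requested absent fraction", {
  tm <- toy_matrix(g = 100, states = 2, reps = 50)
  expect_true(all(simulate_presence_calls(tm$x, 0) == "P"))
  expect_true(all(simulate_presence_calls(tm$x, 1) == "A"))
  calls <- simulate_presence_calls(tm$x, 0.5, seed = 2)
  expect_lt(abs(mean(calls == "A") - 0.5), 0.02)
  expect_identical(calls, simulate_presence_calls(tm$x, 0.5, seed = 2))
})

test_that("per-state statistics are invariant to replicate relabelling", {
  tm <- toy_modular()
  perm <- c(sample(1:4), sample(5:8))
  x2 <- tm$x[, perm]
  d2 <- sample_design(colnames(x2),
                      tm$design$state[match(colnames(x2), tm$design$sample)])
  a <- state_statistics(tm$x, tm$design, tm$modules)
  b <- state_statistics(x2, d2, tm$modules)
  expect_equal(a, b, ignore_attr = TRUE)
})
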