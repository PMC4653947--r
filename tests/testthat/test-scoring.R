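test_that("state statistics match hand cases and the all-pairs oracle", {
  # partners that are exact copies -> mpcc = 1 at that state
  st <- c("S0", "S1")
  samples <- as.vector(t(outer(st, 1:4, paste, sep = "_r")))
  design <- sample_design(samples, rep(st, each = 4))
  base <- c(1, 2, 4, 3)
  x <- rbind(g1 = c(base, rnorm(4)), g2 = c(base, rnorm(4)),
             g3 = c(base, rnorm(4)), g4 = rnorm(8), g5 = rnorm(8),
             g6 = rnorm(8))
  colnames(x) <- samples
  modules <- setNames(c(1, 1, 1, 2, 2, 2), rownames(x))
  st_tab <- state_statistics(x, design, modules)
  expect_equal(st_tab$mpcc[st_tab$gene == "g1" & st_tab$state == "S0"], 1)

  # one partner correlated +1 and one -1 -> mpcc = 1 under |PCC|
  x2 <- rbind(g1 = base, g2 = base * 2 + 1, g3 = -base, g4 = rnorm(4),
              g5 = rnorm(4))
  colnames(x2) <- samples[1:4]
  d2 <- sample_design(samples[1:4], rep("S0", 4))
  m2 <- setNames(c(1, 1, 1, 2, 2), rownames(x2))
  st2 <- state_statistics(x2, d2, m2)
  expect_equal(st2$mpcc[st2$gene == "g1"], 1)

  # 10-gene, 2-module fixture equals exhaustive brute force
  tm <- toy_modular()
  got <- state_statistics(tm$x, tm$design, tm$modules)
  want <- oracle_state_stats(tm$x, tm$design, tm$modules)
  got <- got[order(got$gene, got$state), ]
  want <- want[order(want$gene, want$state), ]
  expect_equal(got$sd, want$sd, tolerance = 1e-12)
  expect_equal(got$mpcc, want$mpcc, tolerance = 1e-12)
  expect_equal(got$opcc, want$opcc, tolerance = 1e-12)
  expect_equal(got$index, want$index, tolerance = 1e-12)

  expect_error(state_statistics(tm$x, tm$design,
                                setNames(c(1, rep(2, 9)), rownames(tm$x))),
               "size 1")
  expect_error(state_statistics(tm$x, tm$design,
                                setNames(rep(0, 10), rownames(tm$x))),
               "nonempty")
})

test_that("transition scores obey the log-ratio identities", {
  mk_stats <- function(I_by_state) {
    do.call(rbind, lapply(names(I_by_state), function(s) {
      data.frame(gene = "g1", state = s, sd = 1, mpcc = 0.5, opcc = 0.5,
                 index = I_by_state[[s]], stringsAsFactors = FALSE)
    }))
  }
  design <- sample_design(paste0("s", 1:9), rep(c("S0", "S1", "S2"), each = 3))
  expect_equal(transition_score(mk_stats(list(S0 = 2, S1 = 2, S2 = 2)),
                                design)$score, 0)
  expect_equal(transition_score(mk_stats(list(S0 = exp(1) * 3, S1 = 3,
                                              S2 = 3)), design)$score, 1)
  sc <- transition_score(mk_stats(list(S0 = 2, S1 = 1, S2 = 4)), design)
  expect_equal(sc$score, log(2))
  expect_identical(sc$argmax_state, "S1")
  # argmax ties break to the earliest state
  sc2 <- transition_score(mk_stats(list(S0 = 2, S1 = 1, S2 = 1)), design)
  expect_identical(sc2$argmax_state, "S1")
  expect_error(transition_score(mk_stats(list(S0 = 2, S1 = 1)), design),
               "missing a state")
})

test_that("scores are invariant to per-gene affine transforms", {
  tm <- toy_modular()
  tm$design <- sample_design(tm$design$sample, tm$design$state)
  base_stats <- state_statistics(tm$x, tm$design, tm$modules)
  base_score <- transition_score(base_stats, tm$design)
  x2 <- tm$x
  x2["g03", ] <- 7.5 * x2["g03", ] + 2
  x2["g08", ] <- 0.2 * x2["g08", ] - 11
  s2 <- state_statistics(x2, tm$design, tm$modules)
  sc2 <- transition_score(s2, tm$design)
  expect_equal(sc2$score, base_score$score, tolerance = 1e-10)
  # mpcc/opcc unchanged; sd scales by |c| uniformly across states
  expect_equal(s2$mpcc, base_stats$mpcc, tolerance = 1e-10)
  expect_equal(s2$opcc, base_stats$opcc, tolerance = 1e-10)
  g3 <- base_stats$gene == "g03"
  expect_equal(s2$sd[g3], 7.5 * base_stats$sd[g3], tolerance = 1e-10)
})

test_that("DVC calling applies the mean + 2 SD rule with sample SD", {
  mk <- function(scores) data.frame(gene = paste0("g", seq_along(scores)),
                                    score = scores,
                                    argmax_state = "S1",
                                    stringsAsFactors = FALSE)
  res <- call_dvc(mk(c(0, 0, 0, 0, 10)))
  expect_equal(res$threshold, 2 + 2 * sqrt(20), tolerance = 1e-12)
  expect_length(res$genes, 0)

  res2 <- call_dvc(mk(c(rep(0, 9), 20)))
  expect_equal(res2$threshold, 2 + 2 * sqrt(40), tolerance = 1e-12)
  expect_identical(res2$genes, "g10")

  expect_message(res3 <- call_dvc(mk(rep(1, 5))), "identical")
  expect_length(res3$genes, 0)
})

test_that("argmax-state summary averages over DVC genes only", {
  flags <- data.frame(gene = paste0("g", 1:4), score = c(9, 9, 0, 0),
                      argmax_state = c("S1", "S2", "S1", "S1"),
                      dvc = c(TRUE, TRUE, FALSE, FALSE))
  out <- max_change_state_summary(list(flags = flags))
  expect_equal(as.numeric(out[c("S1", "S2")]), c(0.5, 0.5))
  expect_equal(sum(out), 1)
  flags$dvc <- FALSE
  expect_message(empty <- max_change_state_summary(list(flags = flags)),
                 "no DVC")
  expect_length(empty, 0)
})

test_that("network export thresholds within-module correlations", {
  st <- "S0"
  samples <- paste0("S0_r", 1:4)
  design <- sample_design(samples, rep(st, 4))
  base <- c(1, 2, 4, 3)
  x <- rbind(g1 = base, g2 = base * 3, g3 = base + 0.001 * c(1, -1, 0, 0),
             g4 = c(1, 3, 2, 5))
  colnames(x) <- samples
  modules <- setNames(c(1, 1, 1, 1), rownames(x))
  net <- export_module_network(x, design, modules, rownames(x), "S0",
                               threshold = 0.95)
  expect_true(all(c("g1", "g2") %in% c(net$source, net$target)))
  # g4 poorly correlated with the rest: no edge reaches 0.95
  expect_false("g4" %in% c(net$source, net$target))
  # k mutually perfect genes -> complete graph
  net3 <- export_module_network(x[1:3, ], design, modules[1:3],
                                rownames(x)[1:3], "S0", threshold = 0.9)
  expect_identical(nrow(net3), 3L)
  expect_message(empty <- export_module_network(x, design, modules,
                                                character(0), "S0"),
                 "empty gene filter")
  expect_identical(nrow(empty), 0L)
})

test_that("dynamics table reports absolute differences against the reference", {
  tm <- toy_modular()
  st_tab <- state_statistics(tm$x, tm$design, tm$modules)
  dyn <- dynamics_table(st_tab, tm$design)
  expect_true(all(dyn$state == "S1"))
  expect_true(all(dyn$dvar >= 0) && all(dyn$dcor >= 0))
  ref <- st_tab[st_tab$state == "S0", ]
  s1 <- st_tab[st_tab$state == "S1", ]
  expect_equal(dyn$dvar, abs(s1$sd - ref$sd))
  expect_equal(dyn$dcor, abs(s1$mpcc - ref$mpcc))
  expect_equal(dyn$log_ratio, log(pmax(ref$index, 1e-6) /
                                    pmax(s1$index, 1e-6)))
})
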