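test_that("Welch t matches the textbook formula and stats::t.test", {
  samples <- c(paste0("S0_r", 1:3), paste0("S1_r", 1:3))
  design <- sample_design(samples, rep(c("S0", "S1"), each = 3))
  x <- matrix(c(2, 4, 6, 1, 2, 3), 1,
              dimnames = list("g1", samples))
  # groups (1,2,3) vs (2,4,6): t = -1.549, df ~ 2.941 (state minus reference)
  res <- welch_t(x, design, "S1")
  expect_equal(res$t, -1.5491933, tolerance = 1e-6)
  expect_equal(res$df, 2.9411765, tolerance = 1e-6)
  expect_equal(res$log_fc, -2)

  # identical groups -> t = 0, p = 1
  xi <- matrix(rep(c(1, 5, 3), 2), 1, dimnames = list("g1", samples))
  ri <- welch_t(xi, design, "S1")
  expect_equal(ri$t, 0)
  expect_equal(ri$p, 1)

  # swapping group roles negates t, keeps p
  xr <- x
  design_sw <- sample_design(samples, rep(c("S1", "S0"), each = 3),
                             state_order = c("S0", "S1"), reference = "S0")
  rs <- welch_t(xr, design_sw, "S1")
  expect_equal(rs$t, -res$t)
  expect_equal(rs$p, res$p)

  # agreement with stats::t.test across random genes
  set.seed(4)
  tm <- toy_matrix(g = 25, states = 2, reps = 6)
  got <- welch_t(tm$x, tm$design, "S1")
  for (i in c(1, 7, 25)) {
    tt <- t.test(tm$x[i, 7:12], tm$x[i, 1:6])
    expect_equal(got$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(got$df[i], unname(tt$parameter), tolerance = 1e-10)
    expect_equal(got$p[i], tt$p.value, tolerance = 1e-10)
  }

  # zero variance in both groups, unequal means -> p = 0 convention
  xz <- matrix(c(1, 1, 1, 2, 2, 2), 1, dimnames = list("g1", samples))
  expect_message(rz <- welch_t(xz, design, "S1"), "zero variance")
  expect_equal(rz$p, 0)
})

test_that("variance F-test matches var.test and its symmetry", {
  samples <- c(paste0("S0_r", 1:8), paste0("S1_r", 1:8))
  design <- sample_design(samples, rep(c("S0", "S1"), each = 8))
  set.seed(5)
  x <- rbind(g1 = c(rnorm(8, sd = 1), 2 * rnorm(8, sd = 1)),
             g2 = rnorm(16))
  colnames(x) <- samples
  res <- f_test_variance(x, design, "S1")
  for (i in 1:2) {
    vt <- var.test(x[i, 9:16], x[i, 1:8])
    expect_equal(res$f[i], unname(vt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], vt$p.value, tolerance = 1e-10)
  }
  expect_identical(res$df1, rep(7, 2))

  # equal sample variances -> F = 1, p = 1
  xe <- matrix(rep(c(1, 2, 3, 4, 2, 3, 1, 4), 2), 1,
               dimnames = list("g1", samples))
  re <- f_test_variance(xe, design, "S1")
  expect_equal(re$f, 1)
  expect_equal(re$p, 1)

  # exchanging groups maps F -> 1/F with the same two-sided p
  design_sw <- sample_design(samples, rep(c("S1", "S0"), each = 8),
                             state_order = c("S0", "S1"))
  rs <- f_test_variance(x, design_sw, "S1")
  expect_equal(rs$f, 1 / res$f, tolerance = 1e-12)
  expect_equal(rs$p, res$p, tolerance = 1e-12)

  xz <- x
  xz[1, 1:8] <- 3
  expect_error(f_test_variance(xz, design, "S1"), "zero reference variance")
})

test_that("BH adjustment matches the step-up oracle and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("DE calls require both the adjusted p and the fold-change rule", {
  # 60 genes: one clear shift below the fc threshold, one huge shift
  samples <- c(paste0("S0_r", 1:8), paste0("S1_r", 1:8))
  design <- sample_design(samples, rep(c("S0", "S1"), each = 8))
  set.seed(8)
  x <- matrix(rnorm(60 * 16, sd = 0.3), 60,
              dimnames = list(sprintf("g%02d", 1:60), samples))
  x[1, 9:16] <- x[1, 9:16] + 8     # extreme shift: drives the threshold
  x[2, 9:16] <- x[2, 9:16] + 0.5   # significant t but modest fold change
  res <- suppressMessages(diff_expression(x, design))
  expect_true("g01" %in% res$de_genes)
  tab2 <- res$table[res$table$gene == "g02", ]
  expect_lt(tab2$q_t, 0.05)
  expect_lt(abs(tab2$log_fc), res$fc_threshold)
  expect_false("g02" %in% res$de_genes)
  expect_equal(res$fc_threshold,
               mean(abs(res$table$log_fc)) + 2 * sd(abs(res$table$log_fc)))
})

test_that("planted differential-variance genes are recovered by the F-test", {
  cfg <- sim_config(seed = 17)
  sim <- simulate_dataset(cfg)
  res <- suppressMessages(diff_expression(sim$matrix, sim$design))
  tg <- sim$truth$transition_genes
  expect_gte(mean(tg %in% res$dv_genes), 0.9)
  # stable-module and background genes are rarely flagged
  others <- setdiff(rownames(sim$matrix), tg)
  expect_lte(mean(others %in% res$dv_genes), 0.05)
})
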