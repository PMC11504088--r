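test_that("log-CPM matches the direct formula and is per-sample scale invariant", {
  m <- matrix(c(0, 10, 90, 5, 20, 75), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  lc <- log_cpm(m)
  expect_equal(lc[, 1], log2(1e6 * c(0, 10, 90) / 100 + 1), ignore_attr = TRUE)
  expect_equal(lc["g1", "s1"], 0)
  m2 <- m; m2[, 2] <- m2[, 2] * 2
  expect_equal(log_cpm(m2)[, 2], lc[, 2])
  expect_error(log_cpm(cbind(m, s3 = c(0, 0, 0))), "zero library")
})

test_that("identical groups give zero fold change and p = 1", {
  m <- matrix(rep(c(1, 2, 3, 4), each = 4), nrow = 4, byrow = TRUE,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:4)))
  groups <- setNames(rep(c("control", "kd"), each = 2), colnames(m))
  de <- de_test(m, groups, "control", "kd")
  expect_equal(de$log2fc, rep(0, 4))
  expect_equal(de$p, rep(1, 4))
  expect_error(de_test(m[, 1:3], groups[1:3], "control", "kd"), "2 samples")
})

test_that("adjusted p-values obey the Benjamini-Hochberg step-up shape", {
  set.seed(11)
  m <- matrix(rnorm(50 * 8, 5), 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  groups <- setNames(rep(c("control", "kd"), each = 4), colnames(m))
  de <- de_test(m, groups, "control", "kd")
  expect_true(all(de$p_adj >= de$p))
  expect_true(all(de$p_adj > 0 & de$p_adj <= 1))
  o <- order(de$p)
  expect_true(all(diff(de$p_adj[o]) >= -1e-15))
})

test_that("planted-shift detection matches the noncentral-t power oracle", {
  set.seed(21)
  n_genes <- 600; n <- 4; disp <- 0.1; mu0 <- 200; fc <- 1
  ctrl <- matrix(rnbinom(n_genes * n, mu = mu0, size = 1 / disp), n_genes)
  kd <- matrix(rnbinom(n_genes * n, mu = mu0 * 2^fc, size = 1 / disp), n_genes)
  m <- cbind(ctrl, kd)
  dimnames(m) <- list(sprintf("g%03d", 1:n_genes),
                      c(sprintf("c%d", 1:n), sprintf("k%d", 1:n)))
  groups <- setNames(rep(c("control", "kd"), each = n), colnames(m))
  # log2(x+1) without library scaling: a global shift would cancel in CPM
  de <- de_test(log2(m + 1), groups, "control", "kd")
  observed <- mean(de$p <= 0.05)
  expected <- welch_power(fc, mu0, disp, n)
  expect_lt(abs(observed - expected), 0.1)
  expect_equal(mean(de$log2fc), fc, tolerance = 0.1)
})

test_that("the fully null simulation keeps the raw false-positive rate nominal", {
  sim <- simulate_null(sim_config(seed = 7))
  de <- de_test(log_cpm(sim$counts_tf1), sim$counts_tf1$groups, "control", "kd")
  fpr <- mean(de$p <= 0.05)
  expect_gte(fpr, 0.03)
  expect_lte(fpr, 0.07)
})

test_that("DEG classification applies inclusive FDR and fold-change gates", {
  de <- mk_de(c("a", "b", "c", "d"),
              c(0.5, 0.30, log2(1.25), -0.5),
              c(0.01, 0.001, 0.01, 0.2))
  cls <- classify_degs(de)
  expect_equal(as.character(cls), c("up", "ns", "up", "ns"))
  expect_equal(sum(table(cls)), nrow(de))
  # literal log2 reading via the config switch
  cls_log <- classify_degs(de, fc_on_log_scale = TRUE, min_linear_fc = 0.4)
  expect_equal(as.character(cls_log["a"]), "up")
  # order invariance
  de2 <- de[c(3, 1, 4, 2), ]
  expect_equal(classify_degs(de2)[names(cls)], cls)
})

test_that("common-DEG overlap counts same-direction genes by biotype", {
  ids <- sprintf("g%02d", 1:10)
  bt <- setNames(rep(c("protein_coding", "lincRNA"), each = 5), ids)
  a <- classify_degs(mk_de(ids, c(rep(1, 4), rep(-1, 4), 0, 0),
                           c(rep(0.01, 8), 1, 1)))
  b_same <- a
  ov <- overlap_degs(a, b_same, bt)
  expect_equal(ov$common[ov$group == "coding" & ov$direction == "up"], 4)
  expect_equal(ov$common[ov$group == "coding" & ov$direction == "down"], 1)
  expect_equal(ov$common[ov$group == "noncoding" & ov$direction == "down"], 3)
  b_disjoint <- classify_degs(mk_de(ids, rep(0, 10), rep(1, 10)))
  expect_true(all(overlap_degs(a, b_disjoint, bt)$common == 0))
})

test_that("deregulogram summarizes concordance over the doubly significant set", {
  ids <- sprintf("g%02d", 1:20)
  de1 <- mk_de(ids, seq(-1, 1, length.out = 20), rep(0.01, 20))
  same <- deregulogram(de1, de1)
  expect_equal(same$summary$r, 1)
  expect_equal(same$summary$pct_concordant, 100)
  de_neg <- de1; de_neg$log2fc <- -de_neg$log2fc
  anti <- deregulogram(de1, de_neg)
  expect_equal(anti$summary$r, -1)
  expect_equal(anti$summary$pct_concordant, 0)
  # fewer than 3 doubly significant genes: r is undefined
  de_ns <- de1; de_ns$p_adj <- c(0.01, 0.01, rep(0.9, 18))
  expect_true(is.na(deregulogram(de1, de_ns)$summary$r))
})

test_that("planted 80% concordance is recovered within sampling error", {
  set.seed(31)
  n <- 500
  ids <- sprintf("g%03d", 1:n)
  fc1 <- rnorm(n, 0, 1); fc1[fc1 == 0] <- 0.1
  flip <- runif(n) > 0.8
  fc2 <- abs(rnorm(n, 0, 1)) * sign(fc1) * ifelse(flip, -1, 1)
  d <- deregulogram(mk_de(ids, fc1, rep(0.01, n)), mk_de(ids, fc2, rep(0.01, n)))
  expect_lt(abs(d$summary$pct_concordant - 80), 5)
})

test_that("the score-ranked trend curve smooths as specified", {
  ids <- sprintf("g%02d", 1:30)
  sc <- setNames(seq_len(30), ids)
  const <- setNames(rep(2.5, 30), ids)
  tr <- score_fc_trend(sc, const, 7)
  expect_equal(tr$trend, rep(2.5, 30))
  fc <- setNames(rnorm(30), ids)
  tr1 <- score_fc_trend(sc, fc, 1)
  expect_equal(tr1$trend, unname(fc[order(sc)]))
  # planted positive fold change on the top score decile
  set.seed(41)
  sc2 <- setNames(runif(200), sprintf("g%03d", 1:200))
  fc2 <- setNames(rnorm(200, 0, 0.3), names(sc2))
  top <- names(sort(sc2, decreasing = TRUE))[1:20]
  fc2[top] <- fc2[top] + 1
  tr2 <- score_fc_trend(sc2, fc2, 20)
  expect_gt(mean(tr2$trend[181:200]), mean(tr2$trend[1:20]))
})
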