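mk_cohort <- function(seed = 61, ng = 40, nt = 15, nn = 10, shift_genes = NULL,
                      shift = 0) {
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(ng))
  base <- rnorm(ng, 6, 1)
  lt <- base + matrix(rnorm(ng * nt), ng)
  if (!is.null(shift_genes)) lt[shift_genes, ] <- lt[shift_genes, ] + shift
  ln <- base + matrix(rnorm(ng * nn), ng)
  dimnames(lt) <- list(ids, sprintf("t%02d", seq_len(nt)))
  dimnames(ln) <- list(ids, sprintf("n%02d", seq_len(nn)))
  list(tumor = 2^lt, normal = 2^ln)
}

test_that("cross-normalization standardizes genes and ignores sample scale", {
  co <- mk_cohort()
  zm <- cross_normalize(co$tumor, co$normal)
  expect_equal(unname(rowMeans(zm$z)), rep(0, nrow(zm$z)), tolerance = 1e-9)
  expect_equal(unname(apply(zm$z, 1, sd)), rep(1, nrow(zm$z)), tolerance = 1e-9)
  co2 <- co; co2$tumor[, 3] <- co2$tumor[, 3] * 10
  zm2 <- cross_normalize(co2$tumor, co2$normal)
  expect_equal(zm2$z, zm$z)
})

test_that("cross-normalization follows the stepwise hand computation", {
  tm <- matrix(c(2, 8, 6, 16), 2, dimnames = list(c("g1", "g2"), c("t1", "t2")))
  nm <- matrix(c(1, 4, 3, 8), 2, dimnames = list(c("g1", "g2"), c("n1", "n2")))
  zm <- cross_normalize(tm, nm, target = 100)
  pooled <- cbind(tm, nm)
  scaled <- sweep(pooled, 2, 100 / apply(pooled, 2, quantile, 0.75), "*")
  lg <- log2(scaled + 1)
  expected <- t(apply(lg, 1, function(x) (x - mean(x)) / sd(x)))
  expect_equal(zm$z, expected)
  expect_equal(unname(zm$class), c("tumor", "tumor", "normal", "normal"))
})

test_that("zero-variance genes and zero-quartile samples are dropped", {
  co <- mk_cohort()
  # an all-zero gene stays constant through scaling and log transform
  co$tumor["g01", ] <- 0; co$normal["g01", ] <- 0
  expect_message(zm <- cross_normalize(co$tumor, co$normal), "zero-variance")
  expect_false("g01" %in% rownames(zm$z))
  co$tumor[, 1] <- 0
  expect_warning(cross_normalize(co$tumor, co$normal), "upper quartile")
})

test_that("metagene scores average panel z-rows", {
  co <- mk_cohort()
  zm <- cross_normalize(co$tumor, co$normal)
  expect_equal(metagene_score(zm, "g05"), zm$z["g05", ])
  panel <- c("g01", "g07", "g11", "g20", "g33")
  expect_equal(metagene_score(zm, panel), colMeans(zm$z[panel, ]))
  zero <- list(z = matrix(0, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3"))),
               class = c(s1 = "tumor", s2 = "tumor", s3 = "normal"))
  class(zero) <- "z_matrix"
  expect_equal(unname(metagene_score(zero, c("a", "b"))), c(0, 0, 0))
  expect_message(metagene_score(zm, c("g05", "nope")), "absent")
  expect_error(metagene_score(zm, "nope"), "no panel gene")
})

test_that("pair-counting AUC reproduces hand examples and edge cases", {
  r <- roc_auc(c(3, 5, 1, 4), rep(c("tumor", "normal"), each = 2))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c("tumor", "normal"), 5))$auc, 0.5)
  sep <- roc_auc(c(10, 11, 12, 1, 2), c(rep("tumor", 3), rep("normal", 2)))
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_error(roc_auc(1:3, rep("tumor", 3)), "both classes")
})

test_that("pair-counting equals the trapezoidal empirical ROC area", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:200, 1)
    labels <- sample(c("tumor", "normal"), n, replace = TRUE,
                     prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    expect_equal(roc_auc(scores, labels)$auc, trap_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is antisymmetric and agrees with an independent ROC package", {
  set.seed(62)
  scores <- rnorm(60)
  labels <- sample(c("tumor", "normal"), 60, replace = TRUE)
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(-scores, labels)$auc, 1 - a, tolerance = 1e-12)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    labels, scores, levels = c("normal", "tumor"), direction = "<")))
  expect_equal(a, as.numeric(ref), tolerance = 1e-12)
})

test_that("stagewise ROC matches pooled when the stage covers all tumors", {
  co <- mk_cohort(63, shift_genes = 1:5, shift = 2)
  zm <- cross_normalize(co$tumor, co$normal)
  sc <- metagene_score(zm, sprintf("g%02d", 1:5))
  stages <- ifelse(zm$class == "tumor", "I", NA)
  tab <- roc_by_stage(sc, zm$class, stages)
  expect_equal(tab$auc[tab$stage == "I"], tab$auc[tab$stage == "pooled"])
  expect_equal(tab$auc_flipped, 1 - tab$auc)
  stages2 <- stages; stages2[which(zm$class == "tumor")[1:2]] <- "II"
  expect_warning(roc_by_stage(sc, zm$class, stages2), "fewer than 3")
})

test_that("a downregulated panel mirrors the upregulated panel's AUC", {
  set.seed(64)
  ng <- 40; nt <- 30; nn <- 20
  ids <- sprintf("g%02d", 1:ng)
  base <- rnorm(ng, 6, 1)
  lt <- base + matrix(rnorm(ng * nt), ng)
  lt[1:5, ] <- lt[1:5, ] + 1.5   # up genes
  lt[6:10, ] <- lt[6:10, ] - 1.5 # down genes, same magnitude
  ln <- base + matrix(rnorm(ng * nn), ng)
  dimnames(lt) <- list(ids, sprintf("t%02d", 1:nt))
  dimnames(ln) <- list(ids, sprintf("n%02d", 1:nn))
  zm <- cross_normalize(2^lt, 2^ln)
  auc_up <- roc_auc(metagene_score(zm, ids[1:5]), zm$class)$auc
  auc_down <- roc_auc(metagene_score(zm, ids[6:10]), zm$class)$auc
  expect_gt(auc_up, 0.8)
  expect_lt(auc_down, 0.2)
  expect_equal(auc_up, 1 - auc_down, tolerance = 0.15)
})

test_that("the log-rank comparison matches a hand-computed table", {
  time <- c(2, 4, 6, 5, 8, 12)
  event <- c(1, 1, 0, 1, 1, 1)
  scores <- c(10, 9, 8, 1, 2, 3)  # median split: first three high
  km <- km_logrank(scores, time, event)
  expect_equal(km$logrank_chi2,
               bf_logrank(time, event, as.integer(scores > median(scores))),
               tolerance = 1e-9)
  expect_equal(km$n_high, 3)
  expect_equal(km$direction, "high")
  expect_true(all(c("time", "surv", "group") %in% names(km$km)))
})

test_that("identical survival in both groups gives chi2 0 and p 1", {
  time <- rep(c(3, 6, 9, 12), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  scores <- rep(c(1, 2), each = 4)  # split puts one copy in each group
  km <- km_logrank(scores, time, event)
  expect_equal(km$logrank_chi2, 0, tolerance = 1e-12)
  expect_equal(km$p, 1)
  expect_error(km_logrank(rep(1, 4), 1:4, c(1, 1, 1, 1)), "one group")
})

test_that("the split is invariant under monotone score transforms", {
  set.seed(65)
  scores <- rnorm(40); time <- rexp(40, 0.1); event <- rbinom(40, 1, 0.7)
  a <- km_logrank(scores, time, event)
  b <- km_logrank(exp(scores), time, event)
  expect_equal(a$logrank_chi2, b$logrank_chi2)
  expect_equal(a$n_high, b$n_high)
})

test_that("two-stratum comparisons agree with the rank-sum test asymptotically", {
  set.seed(66)
  scores <- rnorm(200)
  strata <- rep(c("A", "B"), each = 100)
  sc <- strata_compare(scores, strata)
  w <- wilcox.test(scores[strata == "A"], scores[strata == "B"],
                   exact = FALSE, correct = FALSE)
  expect_lt(abs(sc$p - w$p.value), 0.01)
  shifted <- scores + ifelse(strata == "B", 1, 0)
  expect_lt(strata_compare(shifted, strata)$p, 0.01)
  expect_error(strata_compare(1:3, c("A", "A", "B")), "at least 2")
})

test_that("the multi-cohort panel flags planted effects with direction", {
  eff <- mk_cohort(67, shift_genes = 1:5, shift = 2)
  nul <- mk_cohort(68)
  panel <- sprintf("g%02d", 1:5)
  res <- multicancer_panel(list(gastric = eff, colon = nul, liver = eff), panel)
  expect_true(res$significant[res$cohort == "gastric"])
  expect_equal(res$direction[res$cohort == "gastric"], "up")
  expect_identical(res$p[res$cohort == "gastric"],
                   res$p[res$cohort == "liver"])
  broken <- list(gastric = eff,
                 empty = list(tumor = eff$tumor[, 0], normal = eff$normal))
  expect_warning(multicancer_panel(broken, panel), "missing a class")
})
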