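test_that("a single whole-window peak yields the uniform profile", {
  g <- gene_set("g1", "chr1", 50000, 60000, "+", "protein_coding")
  p <- peak_set("chr1", 48000, 52000, 50000, 1)
  prof <- build_tss_profile(p, g, window_bp = 1000, bin_bp = 100)
  expect_length(prof$weights, 21)  # 2W/bin + 1
  expect_equal(prof$weights, rep(1 / 21, 21))
  expect_equal(sum(prof$weights), 1)
})

test_that("profile weights sum to 1 and concentrate where the binding is", {
  inst <- rand_instance(4, n_peaks = 80, n_genes = 15)
  prof <- build_tss_profile(inst$peaks, inst$genes, 20000, 100)
  expect_equal(sum(prof$weights), 1, tolerance = 1e-12)
  # promoter-only binding on well-separated genes (no window cross-talk):
  # all mass must land within the planted +-1 kb plus the smoother's reach
  starts <- seq(50000, by = 50000, length.out = 15)
  strands <- rep(c("+", "-"), length.out = 15)
  g <- gene_set(sprintf("p%02d", 1:15), "chr1", starts, starts + 10000,
                strands, rep("protein_coding", 15))
  s <- g$tss + sample(-800:800, 15, replace = TRUE)
  pp <- peak_set("chr1", s - 150, s + 150, s, runif(15, 1, 5))
  prof2 <- build_tss_profile(pp, g, 20000, 100)
  inner <- abs(prof2$offsets) <= 1500
  expect_gte(sum(prof2$weights[inner]), 0.95)
  expect_error(build_tss_profile(peak_set("chr9", 1, 100, 50, 1), g, 1000, 100),
               "empty profile")
})

test_that("raw scores equal the per-bin brute-force summation", {
  inst <- rand_instance(5, n_peaks = 60, n_genes = 20)
  prof <- build_tss_profile(inst$peaks, inst$genes, 5000, 100)
  raw <- regulatory_scores(inst$genes, inst$peaks, prof)
  for (i in seq_len(nrow(inst$genes))) {
    expect_equal(unname(raw[inst$genes$gene_id[i]]),
                 bf_raw_score(inst$genes[i, ], inst$peaks, prof),
                 tolerance = 1e-9)
  }
})

test_that("raw score boundary cases: no signal gives 0, full cover gives s", {
  g <- gene_set(c("g1", "g2"), "chr1", c(50000, 500000), c(60000, 510000),
                c("+", "+"), rep("protein_coding", 2))
  p <- peak_set("chr1", 48000, 52000, 50000, 3.5)  # covers g1's whole window
  prof <- build_tss_profile(p, g, 1000, 100)
  raw <- regulatory_scores(g, p, prof)
  expect_equal(unname(raw["g1"]), 3.5)
  expect_equal(unname(raw["g2"]), 0)
})

test_that("zero-signal peaks never change scores; in-window signal never lowers them", {
  inst <- rand_instance(6, n_peaks = 40, n_genes = 10)
  prof <- build_tss_profile(inst$peaks, inst$genes, 10000, 100)
  raw <- regulatory_scores(inst$genes, inst$peaks, prof)
  g1 <- inst$genes[1, ]
  with_zero <- peak_set(
    c(inst$peaks$chrom, "chr1"), c(inst$peaks$start, g1$tss - 50),
    c(inst$peaks$end, g1$tss + 50), c(inst$peaks$summit, g1$tss),
    c(inst$peaks$signal, 0))
  expect_equal(regulatory_scores(inst$genes, with_zero, prof), raw)
  with_pos <- peak_set(
    c(inst$peaks$chrom, "chr1"), c(inst$peaks$start, g1$tss - 10001),
    c(inst$peaks$end, g1$tss + 10001), c(inst$peaks$summit, g1$tss),
    c(inst$peaks$signal, 5))  # covers the whole window: raw must rise by 5
  raw2 <- regulatory_scores(inst$genes, with_pos, prof)
  expect_true(all(raw2 >= raw - 1e-12))
  expect_gt(raw2[g1$gene_id], raw[g1$gene_id])
})

test_that("scores are invariant to gene input order", {
  inst <- rand_instance(7, n_peaks = 40, n_genes = 12)
  prof <- build_tss_profile(inst$peaks, inst$genes, 10000, 100)
  raw <- regulatory_scores(inst$genes, inst$peaks, prof)
  shuf <- inst$genes[sample(nrow(inst$genes)), ]
  class(shuf) <- class(inst$genes)
  raw2 <- regulatory_scores(shuf, inst$peaks, prof)
  expect_equal(raw2[names(raw)], raw)
})

test_that("median calibration maps the positive-score median to 10", {
  raw <- setNames(c(1, 2, 3), c("a", "b", "c"))
  cs <- calibrate_scores(raw)
  expect_equal(cs$scaled, c(5, 10, 15))
  expect_equal(cs$z, (raw - 2) / 1, ignore_attr = TRUE)
  # with zeros present the calibration uses only strictly positive scores
  raw0 <- setNames(c(0, 0, 4, 8, 12), letters[1:5])
  cs0 <- calibrate_scores(raw0)
  expect_equal(cs0$scaled[cs0$gene_id == "d"], 10)
  expect_error(calibrate_scores(setNames(c(2, 2, 2), letters[1:3])), "equal")
  expect_error(calibrate_scores(setNames(c(0, 1, 0), letters[1:3])), "positive")
})

test_that("scaled ranking equals raw ranking on random fixtures", {
  for (seed in 1:3) {
    set.seed(seed)
    raw <- setNames(c(0, rexp(20)), sprintf("g%02d", 0:20))
    cs <- calibrate_scores(raw)
    expect_equal(order(cs$scaled), order(cs$raw))
    expect_true(all(cs$raw == 0 | cs$scaled / cs$raw > 0))
  }
})

test_that("factor combination modes behave and missing genes warn", {
  a <- calibrate_scores(setNames(c(1, 2, 3), c("x", "y", "z")))
  b <- calibrate_scores(setNames(c(3, 2, 1), c("x", "y", "z")))
  cm <- combine_tf_scores(a, b, "mean")
  expect_equal(cm$combined[cm$gene_id == "x"], (5 + 15) / 2)
  expect_equal(combine_tf_scores(a, b, "min")$combined[1], 5)
  expect_equal(combine_tf_scores(a, b, "max")$combined[1], 15)
  b2 <- calibrate_scores(setNames(c(3, 2), c("x", "y")))
  expect_warning(combine_tf_scores(a, b2), "missing")
})

test_that("threshold sets are nested across combination modes", {
  for (seed in 1:3) {
    set.seed(seed)
    ids <- sprintf("g%02d", 1:30)
    a <- calibrate_scores(setNames(rexp(30), ids))
    b <- calibrate_scores(setNames(rexp(30), ids))
    sets <- lapply(c("min", "mean", "max"), function(m) {
      cm <- combine_tf_scores(a, b, m)
      cm$gene_id[cm$combined >= 10]
    })
    expect_true(all(sets[[1]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[3]]))
  }
})
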