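# Independent oracles and tiny fixture builders. These deliberately use
# naive exhaustive computations so they stay independent of the package's
# vectorized implementations.

# exhaustive nearest-TSS search: minimal |summit - tss|, ties by gene_id
bf_nearest <- function(peaks, genes) {
  t(vapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) return(c(gene = NA_character_, dist = NA_character_))
    d <- abs(peaks$summit[i] - g$tss)
    cand <- g$gene_id[d == min(d)]
    best <- sort(cand)[1]
    c(gene = best, dist = as.character(peaks$summit[i] - g$tss[g$gene_id == best]))
  }, c(gene = "", dist = "")))
}

# per-bin brute-force regulatory score: walk every bin of the window,
# summing the signal of peaks covering the bin's genomic position
bf_raw_score <- function(gene, peaks, profile) {
  K <- profile$window_bp %/% profile$bin_bp
  total <- 0
  for (k in -K:K) {
    x <- if (gene$strand == "+") gene$tss + k * profile$bin_bp
         else gene$tss - k * profile$bin_bp
    cover <- peaks$chrom == gene$chrom & peaks$start <= x & x < peaks$end
    total <- total + profile$weights[k + K + 1] * sum(peaks$signal[cover])
  }
  total
}

# trapezoidal area under the empirical ROC curve
trap_auc <- function(scores, labels, positive = "tumor") {
  pos <- labels == positive
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(cuts, function(cc) mean(scores[pos] >= cc), numeric(1))
  fpr <- vapply(cuts, function(cc) mean(scores[!pos] >= cc), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# hand log-rank: observed vs expected events in group 1 over pooled event times
bf_logrank <- function(time, event, group) {
  times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# power of the Welch test on log2-scale data, from the noncentral t
# distribution; NB counts are approximated as lognormal with
# var(ln X) = log(1 + CV^2), CV^2 = 1/mu + dispersion
welch_power <- function(fc_log2, mu, dispersion, n, alpha = 0.05) {
  sd2 <- sqrt(log(1 + 1 / mu + dispersion)) / log(2)
  se <- sd2 * sqrt(2 / n)
  df <- 2 * n - 2
  ncp <- fc_log2 / se
  crit <- qt(1 - alpha / 2, df)
  pt(-crit, df, ncp) + 1 - pt(crit, df, ncp)
}

tiny_genes <- function() {
  gene_set(
    c("g1", "g2", "g3"), "chr1",
    c(100000, 300000, 500000), c(150000, 360000, 520000),
    c("+", "-", "+"),
    c("protein_coding", "lincRNA", "protein_coding")
  )
}

rand_instance <- function(seed, n_peaks = 50, n_genes = 10, L = 1e6) {
  set.seed(seed)
  gs <- sort(sample.int(L - 60000, n_genes))
  genes <- gene_set(sprintf("g%02d", seq_len(n_genes)), "chr1",
                    gs, gs + sample(5000:50000, n_genes, replace = TRUE),
                    sample(c("+", "-"), n_genes, TRUE),
                    sample(c("protein_coding", "lincRNA"), n_genes, TRUE))
  ps <- sample.int(L - 1000, n_peaks)
  w <- sample(100:800, n_peaks, replace = TRUE)
  peaks <- peak_set("chr1", ps, ps + w, ps + w %/% 2, runif(n_peaks, 0.1, 20))
  list(genes = genes, peaks = peaks)
}

# hand-built DE table rows for selection tests
mk_de <- function(gene_id, log2fc, p_adj, biotype = "protein_coding") {
  data.frame(gene_id = gene_id, log2fc = log2fc, p = pmin(p_adj, 1),
             p_adj = p_adj, mean_expr = 5, biotype = biotype,
             stringsAsFactors = FALSE)
}
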