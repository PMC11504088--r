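#' Log2 counts-per-million
#'
#' `log2(1e6 * count / library_size + 1)` per cell; library size is the column
#' sum. Scale-invariant per sample (doubling every count of a sample leaves
#' its values unchanged) and maps zero counts to zero.
#'
#' @param x a [count_matrix()] or a nonnegative genes x samples matrix.
#' @return numeric matrix of log2-CPM values.
#' @export
log_cpm <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$values else x
  lib <- colSums(m)
  if (any(lib == 0)) stop("sample with zero library size: ",
                          paste(colnames(m)[lib == 0], collapse = ", "))
  log2(sweep(m, 2, lib, "/") * 1e6 + 1)
}

#' Gene-wise two-group differential expression (Welch t on log-CPM)
#'
#' For each gene, Welch's two-sample t-test on the normalized values;
#' `log2fc` is mean(treatment) - mean(reference). Genes that are constant in
#' both groups get p = 1 when the means agree (no evidence) and the smallest
#' representable p when they differ (the t statistic is unbounded). P-values
#' are adjusted by Benjamini-Hochberg over all tested genes.
#'
#' @param normalized genes x samples matrix (e.g. from [log_cpm()]).
#' @param groups named character vector mapping samples to condition labels.
#' @param reference,treatment the two condition labels to contrast; defaults
#'   to the first and second level encountered.
#' @param biotype optional named vector of gene biotypes carried through.
#' @return `data.frame` of class `de_table` with `gene_id`, `log2fc`, `p`,
#'   `p_adj`, `mean_expr`, `biotype`.
#' @export
de_test <- function(normalized, groups, reference = NULL, treatment = NULL,
                    biotype = NULL) {
  groups <- groups[colnames(normalized)]
  lv <- unique(groups)
  if (is.null(reference)) reference <- lv[1]
  if (is.null(treatment)) treatment <- setdiff(lv, reference)[1]
  a <- normalized[, groups == reference, drop = FALSE]
  b <- normalized[, groups == treatment, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stop("need at least 2 samples per group")
  lfc <- rowMeans(b) - rowMeans(a)
  p <- vapply(seq_len(nrow(normalized)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (var(x) == 0 && var(y) == 0) {
      if (mean(x) == mean(y)) return(1) else return(.Machine$double.xmin)
    }
    t.test(y, x)$p.value
  }, numeric(1))
  bt <- if (is.null(biotype)) rep(NA_character_, nrow(normalized)) else
    as.character(biotype[rownames(normalized)])
  out <- data.frame(
    gene_id = rownames(normalized), log2fc = lfc, p = p,
    p_adj = p.adjust(p, method = "BH"),
    mean_expr = rowMeans(normalized), biotype = bt,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("de_table", "data.frame")
  out
}

#' Classify genes as up/down/ns at FDR and fold-change gates
#'
#' A gene is `up` when `p_adj <= alpha` and `log2fc >= log2(min_linear_fc)`
#' (both gates inclusive: a fold change exactly at the threshold qualifies),
#' `down` symmetrically, otherwise `ns`. Set `fc_on_log_scale = TRUE` to read
#' the threshold directly in log2 units instead.
#'
#' @param detable a [de_test()] result (or any data frame with `gene_id`,
#'   `log2fc`, `p_adj`).
#' @param alpha FDR threshold (default 0.05).
#' @param min_linear_fc linear fold-change threshold (default 1.25).
#' @param fc_on_log_scale interpret `min_linear_fc` as log2 units.
#' @return named factor (`up`/`down`/`ns`) over genes.
#' @export
classify_degs <- function(detable, alpha = 0.05, min_linear_fc = 1.25,
                          fc_on_log_scale = FALSE) {
  thr <- if (fc_on_log_scale) min_linear_fc else log2(min_linear_fc)
  cls <- rep("ns", nrow(detable))
  sig <- detable$p_adj <= alpha
  cls[sig & detable$log2fc >= thr] <- "up"
  cls[sig & detable$log2fc <= -thr] <- "down"
  setNames(factor(cls, levels = c("up", "down", "ns")), detable$gene_id)
}

#' Commonly affected genes between two knockdowns
#'
#' Counts genes called in the same direction in both classifications, split by
#' coding vs non-coding biotype.
#'
#' @param class_a,class_b named factors from [classify_degs()] over the same
#'   gene universe.
#' @param biotype named character vector of biotypes per gene.
#' @return `data.frame` with `group` (coding/noncoding), `direction`, `common`.
#' @export
overlap_degs <- function(class_a, class_b, biotype) {
  genes <- names(class_a)
  stopifnot(setequal(genes, names(class_b)))
  class_b <- class_b[genes]
  grp <- ifelse(biotype[genes] == "protein_coding", "coding", "noncoding")
  out <- expand.grid(group = c("coding", "noncoding"),
                     direction = c("up", "down"), stringsAsFactors = FALSE)
  out$common <- mapply(function(g, d) {
    sum(class_a == d & class_b == d & grp == g)
  }, out$group, out$direction)
  out
}

#' Deregulogram: fold-change concordance between two knockdowns
#'
#' Per-gene record of both contrasts' fold changes, a significance class
#' (`both`, `tf1_only`, `tf2_only`, `neither` at `p_adj <= alpha`) and a
#' concordance flag (equal fold-change signs; undefined when either is zero).
#' The summary reports Pearson's r of the fold changes and the percentage of
#' concordant genes over the `both`-significant set (r is NA when fewer than
#' 3 genes are significant in both).
#'
#' @param detable_a,detable_b [de_test()] results over a shared universe.
#' @param alpha FDR threshold for the significance classes.
#' @return list with `records` (`data.frame`) and `summary`
#'   (`r`, `pct_concordant`, `n_both`).
#' @export
deregulogram <- function(detable_a, detable_b, alpha = 0.05) {
  stopifnot(setequal(detable_a$gene_id, detable_b$gene_id))
  b <- detable_b[match(detable_a$gene_id, detable_b$gene_id), ]
  sig_a <- detable_a$p_adj <= alpha
  sig_b <- b$p_adj <= alpha
  sig_class <- ifelse(sig_a & sig_b, "both",
               ifelse(sig_a, "tf1_only", ifelse(sig_b, "tf2_only", "neither")))
  conc <- ifelse(detable_a$log2fc != 0 & b$log2fc != 0,
                 sign(detable_a$log2fc) == sign(b$log2fc), NA)
  rec <- data.frame(
    gene_id = detable_a$gene_id, fc_tf1 = detable_a$log2fc, fc_tf2 = b$log2fc,
    sig_class = sig_class, concordant = conc, stringsAsFactors = FALSE
  )
  both <- rec[rec$sig_class == "both", ]
  r <- if (nrow(both) >= 3) cor(both$fc_tf1, both$fc_tf2) else NA_real_
  pc <- if (nrow(both)) 100 * mean(both$concordant, na.rm = TRUE) else NA_real_
  list(records = rec,
       summary = list(r = r, pct_concordant = pc, n_both = nrow(both)))
}

#' Smoothed deregulation trend along the regulatory-score ranking
#'
#' Sorts genes by ascending regulatory score and smooths the fold changes with
#' a centred rolling mean. At position i the window is shrunk symmetrically to
#' `[i - k, i + k]` with `k = min(floor(window_genes/2), i - 1, n - i)`, so a
#' window of 1 returns the sorted fold changes unchanged and a constant fold
#' change yields a constant curve.
#'
#' @param scores named numeric vector of (combined scaled) regulatory scores.
#' @param fcs named numeric vector of log2 fold changes, same universe.
#' @param window_genes nominal rolling-window width (default 200).
#' @return `data.frame` with `gene_id`, `rank`, `score`, `fc`, `trend`.
#' @export
score_fc_trend <- function(scores, fcs, window_genes = 200L) {
  stopifnot(window_genes >= 1, setequal(names(scores), names(fcs)))
  fcs <- fcs[names(scores)]
  o <- order(scores, names(scores))  # ties broken by gene_id for determinism
  s <- scores[o]; f <- fcs[o]
  n <- length(f)
  h <- window_genes %/% 2L
  cs <- cumsum(c(0, f))
  i <- seq_len(n)
  k <- pmin(h, i - 1L, n - i)
  trend <- (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
  data.frame(
    gene_id = names(s), rank = i, score = as.numeric(s), fc = as.numeric(f),
    trend = trend, stringsAsFactors = FALSE, row.names = NULL
  )
}
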