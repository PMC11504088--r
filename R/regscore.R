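#' Build the average TSS-centred binding profile (TIP-style weights)
#'
#' Bins the window `[-window_bp, window_bp]` around every TSS at `bin_bp`
#' resolution in strand-oriented offsets. The signal of a bin for one gene is
#' the summed `signal` of all peaks whose interval covers the bin's genomic
#' position; the profile is the mean of these per-gene signals over all genes,
#' smoothed with a centred moving average (`smooth_bins` wide, shrunk at the
#' edges) and normalized to sum to 1. The resulting weights are the
#' characteristic binding footprint of the factor and concentrate near the TSS
#' for promoter-bound factors.
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_set()].
#' @param window_bp half-width of the TSS window (default 100 kb).
#' @param bin_bp bin size in bp (default 100).
#' @param smooth_bins width of the moving-average smoother (odd, default 5).
#' @return object of class `weight_profile`: list with `window_bp`, `bin_bp`,
#'   `offsets` (strand-oriented, bp) and `weights` summing to 1.
#' @export
build_tss_profile <- function(peaks, genes, window_bp = 100000L, bin_bp = 100L,
                              smooth_bins = 5L) {
  acc <- .bin_cover(peaks, genes, window_bp, bin_bp)
  nb <- 2L * (window_bp %/% bin_bp) + 1L
  delta <- numeric(nb + 1L)
  if (nrow(acc)) {
    for (r in seq_len(nrow(acc))) {
      delta[acc$k1[r]] <- delta[acc$k1[r]] + acc$signal[r]
      delta[acc$k2[r] + 1L] <- delta[acc$k2[r] + 1L] - acc$signal[r]
    }
  }
  prof <- cumsum(delta[seq_len(nb)]) / nrow(genes)
  if (sum(prof) == 0) stop("empty profile: no peak overlaps any gene window")
  sm <- .moving_average(prof, smooth_bins)
  K <- window_bp %/% bin_bp
  out <- list(
    window_bp = as.integer(window_bp), bin_bp = as.integer(bin_bp),
    smooth_bins = as.integer(smooth_bins),
    offsets = (-K:K) * as.integer(bin_bp),
    weights = sm / sum(sm)
  )
  class(out) <- "weight_profile"
  out
}

# covered bin index ranges (1-based, within 1..nbins) for every overlapping
# gene x peak pair; bin k corresponds to strand-oriented offset (k - K - 1)*bin
.bin_cover <- function(peaks, genes, window_bp, bin_bp) {
  stopifnot(inherits(peaks, "peak_set"), inherits(genes, "gene_set"))
  K <- window_bp %/% bin_bp
  res <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (!nrow(p)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(g$tss - window_bp, g$tss + window_bp),
      IRanges::IRanges(p$start, p$end - 1L)
    )
    if (!length(hits)) next
    gi <- S4Vectors::queryHits(hits); pi <- S4Vectors::subjectHits(hits)
    tss <- g$tss[gi]; s <- p$start[pi]; e <- p$end[pi]
    plus <- g$strand[gi] == "+"
    k1 <- ifelse(plus, ceiling((s - tss) / bin_bp), ceiling((tss - e + 1L) / bin_bp))
    k2 <- ifelse(plus, floor((e - 1L - tss) / bin_bp), floor((tss - s) / bin_bp))
    k1 <- pmax(k1, -K); k2 <- pmin(k2, K)
    keep <- k1 <= k2
    res[[ch]] <- data.frame(
      gene_id = g$gene_id[gi][keep],
      k1 = as.integer(k1[keep] + K + 1L), k2 = as.integer(k2[keep] + K + 1L),
      signal = p$signal[pi][keep], stringsAsFactors = FALSE
    )
  }
  if (!length(res)) {
    return(data.frame(gene_id = character(), k1 = integer(), k2 = integer(),
                      signal = numeric()))
  }
  do.call(rbind, res)
}

.moving_average <- function(x, w) {
  if (w <= 1) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Raw regulatory scores for all genes
#'
#' The raw score of a gene is the profile-weighted sum of binding signal over
#' its TSS window: `sum_d weights(d) * signal_gene(d)`. It is zero exactly when
#' no peak signal falls in the window, and a peak covering the whole window
#' with signal `s` contributes `s` (the weights sum to 1).
#'
#' @param genes a [gene_set()].
#' @param peaks a [peak_set()].
#' @param profile a [build_tss_profile()] result (same window/bin settings).
#' @return named numeric vector of raw scores, one per gene.
#' @export
regulatory_scores <- function(genes, peaks, profile) {
  stopifnot(inherits(profile, "weight_profile"))
  acc <- .bin_cover(peaks, genes, profile$window_bp, profile$bin_bp)
  raw <- setNames(numeric(nrow(genes)), genes$gene_id)
  if (nrow(acc)) {
    cw <- c(0, cumsum(profile$weights))
    contrib <- acc$signal * (cw[acc$k2 + 1L] - cw[acc$k1])
    agg <- tapply(contrib, acc$gene_id, sum)
    raw[names(agg)] <- as.numeric(agg)
  }
  raw
}

#' Raw regulatory score of a single gene
#'
#' @param gene one-row [gene_set()] (or a row index into `genes` semantics is
#'   not supported; pass a subset).
#' @param peaks a [peak_set()].
#' @param profile a [build_tss_profile()] result.
#' @return scalar raw score.
#' @export
gene_raw_score <- function(gene, peaks, profile) {
  stopifnot(inherits(gene, "gene_set"), nrow(gene) == 1)
  unname(regulatory_scores(gene, peaks, profile))
}

#' Calibrate raw regulatory scores
#'
#' Produces the z-score over all genes and a median-calibrated scale:
#' `scaled = 10 * raw / median(raw[raw > 0])`, so that a gene sits at
#' `scaled >= 10` exactly when its raw score reaches the median of the
#' strictly positive scores. The scaled score is a positive multiple of the
#' raw score, so rankings are identical.
#'
#' @param raw named numeric vector from [regulatory_scores()].
#' @param tf factor label stored with the result.
#' @return `data.frame` of class `regulatory_score` with columns `gene_id`,
#'   `tf`, `raw`, `z`, `scaled`.
#' @export
calibrate_scores <- function(raw, tf = "TF") {
  if (sum(raw > 0) < 2) stop("need at least 2 genes with positive raw score")
  if (sd(raw) == 0) stop("all raw scores equal; z-score undefined")
  med <- median(raw[raw > 0])
  out <- data.frame(
    gene_id = names(raw), tf = tf, raw = as.numeric(raw),
    z = (raw - mean(raw)) / sd(raw),
    scaled = 10 * raw / med,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("regulatory_score", "data.frame")
  out
}

#' Combine two factors' calibrated scores per gene
#'
#' @param score_a,score_b [calibrate_scores()] results for the two factors.
#' @param mode `"mean"` (default), `"min"` or `"max"` elementwise combination
#'   of the scaled scores. Genes missing from one factor are treated as raw 0
#'   with a warning.
#' @return `data.frame` with `gene_id`, `scaled_a`, `scaled_b`, `combined`.
#' @export
combine_tf_scores <- function(score_a, score_b, mode = c("mean", "min", "max")) {
  mode <- match.arg(mode)
  universe <- union(score_a$gene_id, score_b$gene_id)
  missing_n <- sum(!(universe %in% score_a$gene_id)) +
    sum(!(universe %in% score_b$gene_id))
  if (missing_n > 0) {
    warning(missing_n, " gene(s) missing from one factor; treated as score 0")
  }
  a <- setNames(rep(0, length(universe)), universe)
  a[score_a$gene_id] <- score_a$scaled
  b <- setNames(rep(0, length(universe)), universe)
  b[score_b$gene_id] <- score_b$scaled
  comb <- switch(mode,
    mean = (a + b) / 2,
    min = pmin(a, b),
    max = pmax(a, b)
  )
  universe <- sort(universe)
  data.frame(
    gene_id = universe, scaled_a = a[universe], scaled_b = b[universe],
    combined = comb[universe], stringsAsFactors = FALSE, row.names = NULL
  )
}
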