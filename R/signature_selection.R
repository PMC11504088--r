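#' Select metagene signatures from combined binding and knockdown evidence
#'
#' A gene is admitted when (i) its combined scaled regulatory score is at
#' least `score_min`, (ii) both knockdown contrasts classify it in the same
#' non-`ns` direction at (`alpha`, `min_linear_fc`), i.e. it is
#' unidirectionally and significantly affected by both factors, and
#' (iii) implicitly through (ii), its fold change reaches the threshold in
#' both contrasts. Admitted genes split into four disjoint lists by direction
#' (up/down) and biotype group (`protein_coding` vs everything else).
#'
#' @param scores [combine_tf_scores()] result (or named numeric vector of
#'   combined scores).
#' @param detable_a,detable_b [de_test()] results for the two knockdowns.
#' @param biotype named character vector of biotypes per gene.
#' @param score_min combined-score threshold (default 10, the median-calibrated
#'   scale's midpoint).
#' @param alpha FDR gate (default 0.05).
#' @param min_linear_fc linear fold-change gate (default 1.25).
#' @param equal_fc_tol optional stricter mode: additionally require
#'   `|fc_tf1 - fc_tf2| <= equal_fc_tol` (log2 units).
#' @return object of class `signature_panel`: lists `coding_up`,
#'   `coding_down`, `noncoding_up`, `noncoding_down` plus a `provenance`
#'   data frame recording the admitting evidence per gene.
#' @export
select_signature <- function(scores, detable_a, detable_b, biotype,
                             score_min = 10, alpha = 0.05,
                             min_linear_fc = 1.25, equal_fc_tol = NULL) {
  if (is.data.frame(scores)) scores <- setNames(scores$combined, scores$gene_id)
  cls_a <- classify_degs(detable_a, alpha, min_linear_fc)
  cls_b <- classify_degs(detable_b, alpha, min_linear_fc)
  genes <- intersect(names(cls_a), names(cls_b))
  genes <- intersect(genes, names(scores))
  cls_a <- cls_a[genes]; cls_b <- cls_b[genes]
  fc_a <- setNames(detable_a$log2fc, detable_a$gene_id)[genes]
  fc_b <- setNames(detable_b$log2fc, detable_b$gene_id)[genes]
  ok <- scores[genes] >= score_min & cls_a != "ns" & cls_a == cls_b
  if (!is.null(equal_fc_tol)) {
    ok <- ok & abs(fc_a - fc_b) <= equal_fc_tol
  }
  sel <- sort(genes[ok])
  if (!length(sel)) warning("no gene passes all selection criteria; empty panel")
  dir <- as.character(cls_a[sel])
  coding <- biotype[sel] == "protein_coding"
  prov <- data.frame(
    gene_id = sel,
    score = as.numeric(scores[sel]),
    fc_tf1 = as.numeric(fc_a[sel]), fc_tf2 = as.numeric(fc_b[sel]),
    p_adj_tf1 = setNames(detable_a$p_adj, detable_a$gene_id)[sel],
    p_adj_tf2 = setNames(detable_b$p_adj, detable_b$gene_id)[sel],
    direction = dir,
    biotype = as.character(biotype[sel]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- list(
    coding_up = sel[coding & dir == "up"],
    coding_down = sel[coding & dir == "down"],
    noncoding_up = sel[!coding & dir == "up"],
    noncoding_down = sel[!coding & dir == "down"],
    provenance = prov
  )
  class(out) <- "signature_panel"
  out
}

#' Summary counts for a signature panel
#'
#' @param panel a [select_signature()] result.
#' @return one-row `data.frame` with the four quadrant counts, `total` and
#'   `pct_up` (percentage of admitted genes that are upregulated).
#' @export
panel_report <- function(panel) {
  stopifnot(inherits(panel, "signature_panel"))
  cu <- length(panel$coding_up); cd <- length(panel$coding_down)
  nu <- length(panel$noncoding_up); nd <- length(panel$noncoding_down)
  total <- cu + cd + nu + nd
  data.frame(
    coding_up = cu, coding_down = cd,
    noncoding_up = nu, noncoding_down = nd,
    total = total,
    pct_up = if (total) 100 * (cu + nu) / total else 0
  )
}

#' @export
print.signature_panel <- function(x, ...) {
  rep <- panel_report(x)
  cat("signature panel:", rep$total, "genes (",
      rep$coding_up, "coding up,", rep$coding_down, "coding down,",
      rep$noncoding_up, "non-coding up,", rep$noncoding_down,
      "non-coding down )\n")
  invisible(x)
}
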