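#' Annotate peaks to their nearest-TSS gene
#'
#' Each peak is assigned to the gene whose TSS is closest to the peak summit
#' (ties broken by lexicographic `gene_id`). The signed distance is
#' `summit - TSS`, negated for `-` strand genes so that upstream of the gene
#' is always negative. The distance category is binned on `|distance|` with
#' left-closed right-open bins; the genic feature is `exon`/`intron` when the
#' summit falls inside the assigned gene body (`exon` only when exon intervals
#' are supplied), `downstream` within `downstream_bp` past the gene end, and
#' otherwise `promoter` or `intergenic` according to the distance category.
#'
#' Peaks on chromosomes carrying no genes are kept with `gene_id = NA` and the
#' most distal category, and reported via `message()`.
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_set()].
#' @param breaks_kb distance bin edges in kb (default `c(0,1,3,5,10,100,Inf)`).
#' @param downstream_bp window past the gene 3' end called `downstream`.
#' @param exons optional data.frame (`gene_id`, `start`, `end`) of exon
#'   intervals used to split genic hits into exon vs intron.
#' @return `data.frame` of class `peak_annotation`.
#' @export
assign_peaks <- function(peaks, genes, breaks_kb = .default_breaks_kb,
                         downstream_bp = 3000L, exons = NULL) {
  stopifnot(inherits(peaks, "peak_set"), inherits(genes, "gene_set"))
  labels <- .category_labels(breaks_kb)
  n <- nrow(peaks)
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)

  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) {
      message(length(pi), " peak(s) on chromosome ", ch, " with no genes")
      next
    }
    # one representative (lexicographically first gene_id) per distinct TSS
    o <- order(g$tss, g$gene_id)
    g <- g[o, , drop = FALSE]
    keep <- !duplicated(g$tss)
    tss <- g$tss[keep]
    rep_id <- g$gene_id[keep]
    s <- peaks$summit[pi]
    i <- findInterval(s, tss)
    dl <- ifelse(i >= 1, s - tss[pmax(i, 1L)], Inf)
    dr <- ifelse(i < length(tss), tss[pmin(i + 1L, length(tss))] - s, Inf)
    use_left <- dl < dr | (dl == dr & rep_id[pmax(i, 1L)] <= rep_id[pmin(i + 1L, length(tss))])
    j <- ifelse(use_left, pmax(i, 1L), pmin(i + 1L, length(tss)))
    gene_id[pi] <- rep_id[j]
    dist[pi] <- s - tss[j]
  }

  gi <- match(gene_id, genes$gene_id)
  signed <- ifelse(!is.na(gi) & genes$strand[gi] == "-", -dist, dist)
  category <- ifelse(
    is.na(signed), labels[length(labels)],
    labels[findInterval(abs(signed), breaks_kb * 1000)]
  )

  feature <- rep("intergenic", n)
  prom <- labels[grepl("^prom_", labels)]
  feature[category %in% prom] <- "promoter"
  in_body <- !is.na(gi) & peaks$summit >= genes$start[gi] & peaks$summit < genes$end[gi]
  feature[in_body] <- "intron"
  if (!is.null(exons)) {
    for (k in which(in_body)) {
      ex <- exons[exons$gene_id == gene_id[k], , drop = FALSE]
      if (nrow(ex) && any(peaks$summit[k] >= ex$start & peaks$summit[k] < ex$end)) {
        feature[k] <- "exon"
      }
    }
  }
  past_end <- !is.na(gi) & !in_body &
    ifelse(genes$strand[gi] == "+",
           peaks$summit >= genes$end[gi] & peaks$summit < genes$end[gi] + downstream_bp,
           peaks$summit < genes$start[gi] & peaks$summit >= genes$start[gi] - downstream_bp)
  feature[past_end] <- "downstream"

  out <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    summit = peaks$summit, signal = peaks$signal,
    gene_id = gene_id, distance = signed,
    category = factor(category, levels = labels),
    feature = feature, stringsAsFactors = FALSE
  )
  class(out) <- c("peak_annotation", "data.frame")
  out
}

#' Distance-category distribution of annotated peaks
#'
#' @param annotations a [assign_peaks()] result.
#' @return `data.frame` with `category`, `count`, `pct`; percentages sum to 100.
#' @export
tss_distribution <- function(annotations) {
  stopifnot(inherits(annotations, "peak_annotation"))
  if (!nrow(annotations)) stop("empty annotation list")
  tab <- table(annotations$category)
  data.frame(
    category = names(tab),
    count = as.integer(tab),
    pct = 100 * as.integer(tab) / nrow(annotations),
    stringsAsFactors = FALSE
  )
}

# bp of genome whose nearest-TSS distance falls in each |distance| bin.
# Each TSS owns a cell bounded by midpoints to its neighbours (and the
# chromosome ends); within a cell the distance rises linearly along both arms.
.category_territory <- function(genes, chrom_lengths, breaks_kb) {
  edges <- breaks_kb * 1000
  labels <- .category_labels(breaks_kb)
  terr <- setNames(numeric(length(labels)), labels)
  for (ch in names(chrom_lengths)) {
    tss <- sort(unique(genes$tss[genes$chrom == ch]))
    if (!length(tss)) next
    L <- chrom_lengths[[ch]]
    bounds <- c(0, (tss[-length(tss)] + tss[-1]) / 2, L)
    arms <- c(tss - bounds[-length(bounds)], bounds[-1] - tss)  # arm lengths
    arms <- arms[arms > 0]
    for (b in seq_along(labels)) {
      lo <- edges[b]; hi <- edges[b + 1]
      terr[b] <- terr[b] + sum(pmax(0, pmin(arms, hi) - lo))
    }
  }
  terr
}

#' Territory-normalized peak enrichment per distance category
#'
#' Compares the peak density (peaks per Mb) inside each distance category's
#' genomic territory with the genome-wide density. The territory of a category
#' is the total bp whose nearest-TSS distance falls in that bin, so a ratio of
#' 1 means the category holds exactly the peaks expected from its size.
#'
#' @param annotations a [assign_peaks()] result.
#' @param genes the [gene_set()] used for annotation.
#' @param genome_length total genome length; a named per-chromosome vector, or
#'   a single number when the genes lie on one chromosome.
#' @param breaks_kb distance bin edges (must match the annotation's).
#' @return `data.frame` with per-category counts, territory (Mb), densities and
#'   the enrichment `ratio` (NA where the territory is empty).
#' @export
annotation_enrichment <- function(annotations, genes, genome_length,
                                  breaks_kb = .default_breaks_kb) {
  stopifnot(inherits(annotations, "peak_annotation"), inherits(genes, "gene_set"))
  if (any(genome_length <= 0)) stop("genome_length must be positive")
  chroms <- unique(genes$chrom)
  if (is.null(names(genome_length))) {
    if (length(genome_length) != 1 || length(chroms) != 1) {
      stop("genome_length must be named per chromosome when several are present")
    }
    genome_length <- setNames(genome_length, chroms)
  }
  terr <- .category_territory(genes, genome_length, breaks_kb)
  tab <- table(factor(annotations$category, levels = names(terr)))
  total_density <- nrow(annotations) / (sum(genome_length) / 1e6)
  dens <- ifelse(terr > 0, as.integer(tab) / (terr / 1e6), NA_real_)
  data.frame(
    category = names(terr),
    count = as.integer(tab),
    territory_mb = as.numeric(terr) / 1e6,
    density = dens,
    ratio = dens / total_density,
    stringsAsFactors = FALSE
  )
}

#' Relative distance between two peak sets
#'
#' For every midpoint of `a` lying within the span of `b`'s midpoints on the
#' same chromosome, the relative distance is `min(d_left, d_right) /
#' (d_left + d_right)` to the two flanking `b` midpoints. Under spatial
#' independence the values are uniform on \[0, 0.5\]; co-occurring sets pile up
#' near 0.
#'
#' @param a,b [peak_set()] objects.
#' @param nbins number of histogram bins over \[0, 0.5\].
#' @return list with `rel` (numeric vector) and `hist` (`data.frame` of
#'   `bin_low`, `bin_high`, `count`, `frac`).
#' @export
reldist <- function(a, b, nbins = 50L) {
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"))
  rel <- numeric(0)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    am <- (a$start[a$chrom == ch] + a$end[a$chrom == ch]) %/% 2L
    bm <- sort(unique((b$start[b$chrom == ch] + b$end[b$chrom == ch]) %/% 2L))
    if (length(bm) < 2) {
      warning("chromosome ", ch, " has fewer than 2 reference midpoints; skipped")
      next
    }
    am <- am[am >= bm[1] & am <= bm[length(bm)]]
    if (!length(am)) next
    i <- pmin(findInterval(am, bm), length(bm) - 1L)
    dl <- am - bm[i]
    dr <- bm[i + 1L] - am
    r <- pmin(dl, dr) / (dl + dr)
    r[dl == 0 | dr == 0] <- 0  # midpoint coincides with a reference midpoint
    rel <- c(rel, r)
  }
  breaks <- seq(0, 0.5, length.out = nbins + 1L)
  cnt <- tabulate(pmin(findInterval(rel, breaks), nbins), nbins)
  list(
    rel = rel,
    hist = data.frame(
      bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
      count = cnt, frac = if (length(rel)) cnt / length(rel) else rep(0, nbins)
    )
  )
}
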