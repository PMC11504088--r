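#' Construct a gene set
#'
#' A gene set is the annotation universe of the pipeline: one row per gene with
#' 0-based half-open coordinates, strand, biotype and a single canonical TSS
#' (the most upstream position of the gene: `start` on `+`, `end` on `-`).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome names.
#' @param start,end integer coordinates, 0-based half-open (`start < end`).
#' @param strand `"+"` or `"-"`.
#' @param biotype one of `"protein_coding"`, `"lincRNA"`, `"pseudogene"`,
#'   `"other_noncoding"`. Missing values default to `"other_noncoding"` with a
#'   warning.
#' @return A `data.frame` of class `gene_set` with a derived `tss` column.
#' @export
gene_set <- function(gene_id, chrom, start, end, strand, biotype) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id: ", paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) stop("non-integer gene coordinates")
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop("gene ", gene_id[bad], ": start >= end")
  }
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  biotype <- as.character(biotype)
  if (any(is.na(biotype) | biotype == "")) {
    warning("missing biotype set to 'other_noncoding'")
    biotype[is.na(biotype) | biotype == ""] <- "other_noncoding"
  }
  if (!all(biotype %in% .biotypes)) {
    stop("unknown biotype: ", paste(setdiff(biotype, .biotypes), collapse = ", "))
  }
  df <- data.frame(
    gene_id = gene_id, chrom = as.character(chrom),
    start = start, end = end, strand = as.character(strand),
    biotype = biotype,
    tss = ifelse(strand == "+", start, end),
    stringsAsFactors = FALSE
  )
  class(df) <- c("gene_set", "data.frame")
  df
}

#' Read gene models from TSV or GTF
#'
#' The TSV dialect is a header line `gene_id chrom start end strand biotype`
#' with 0-based half-open coordinates. GTF input (1-based inclusive) is
#' converted on read; multi-transcript genes collapse to one model per gene
#' with the most upstream TSS and the union extent of its features.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gtf"`.
#' @return A [gene_set()].
#' @export
read_gene_models <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
    need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
    if (!all(need %in% names(df))) {
      stop("gene TSV must have columns: ", paste(need, collapse = ", "))
    }
    start <- suppressWarnings(as.integer(df$start))
    end <- suppressWarnings(as.integer(df$end))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad)) {
      stop("malformed gene line ", bad[1] + 1L, " in ", path)  # +1 for header
    }
    return(gene_set(df$gene_id, df$chrom, start, end, df$strand, df$biotype))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(gr)
  if (is.null(meta$gene_id)) stop("GTF lacks gene_id attribute")
  bt <- meta$gene_biotype
  if (is.null(bt)) bt <- meta$gene_type
  if (is.null(bt)) bt <- rep(NA_character_, nrow(meta))
  # collapse to one record per gene: union extent, most upstream TSS via strand
  sp <- split(seq_len(nrow(meta)), meta$gene_id)
  rows <- lapply(sp, function(i) {
    data.frame(
      gene_id = meta$gene_id[i[1]],
      chrom = as.character(meta$seqnames[i[1]]),
      start = min(meta$start[i]) - 1L,  # GTF 1-based inclusive -> 0-based half-open
      end = max(meta$end[i]),
      strand = as.character(meta$strand[i[1]]),
      biotype = .map_biotype(bt[i[1]]),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  gene_set(df$gene_id, df$chrom, df$start, df$end, df$strand, df$biotype)
}

.map_biotype <- function(x) {
  if (is.na(x) || x == "") return(NA_character_)
  if (x == "protein_coding") return("protein_coding")
  if (x %in% c("lincRNA", "lncRNA")) return("lincRNA")
  if (grepl("pseudogene", x)) return("pseudogene")
  "other_noncoding"
}

#' Write gene models to the canonical TSV dialect
#'
#' @param genes a [gene_set()].
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  stopifnot(inherits(genes, "gene_set"))
  out <- genes[, c("gene_id", "chrom", "start", "end", "strand", "biotype")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a peak set
#'
#' One row per ChIP interval with a summit (binding-point estimate) and a
#' nonnegative enrichment signal. Coordinates are 0-based half-open and the
#' summit must satisfy `start <= summit < end`.
#'
#' @param chrom,start,end interval coordinates.
#' @param summit absolute summit position.
#' @param signal nonnegative enrichment value.
#' @param name optional peak names.
#' @return A `data.frame` of class `peak_set`.
#' @export
peak_set <- function(chrom, start, end, summit, signal, name = NULL) {
  start <- as.integer(start); end <- as.integer(end); summit <- as.integer(summit)
  if (any(start >= end)) stop("peak with start >= end at row ", which(start >= end)[1])
  if (any(summit < start | summit >= end)) {
    stop("summit outside peak interval at row ", which(summit < start | summit >= end)[1])
  }
  signal <- as.numeric(signal)
  if (any(is.na(signal)) || any(signal < 0)) stop("peak signal must be nonnegative")
  if (is.null(name)) name <- sprintf("peak_%d", seq_along(start))
  df <- data.frame(
    chrom = as.character(chrom), start = start, end = end,
    name = as.character(name), signal = signal, summit = summit,
    stringsAsFactors = FALSE
  )
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Read a peak file (narrowPeak or BED6)
#'
#' For narrowPeak the summit is `start + offset` (column 10); an offset of -1
#' falls back to the floor interval midpoint, as does BED6 which carries no
#' summit. Signal is `signalValue` (narrowPeak) or the BED score column.
#'
#' @param path file path.
#' @param format `"narrowPeak"` or `"bed6"`.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed6")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (format == "narrowPeak") {
    if (ncol(df) < 10) stop("narrowPeak requires 10 columns")
    names(df)[1:10] <- c("chrom", "start", "end", "name", "score", "strand",
                         "signalValue", "pValue", "qValue", "peak")
    if (any(df$start >= df$end)) {
      stop("peak line ", which(df$start >= df$end)[1], ": start >= end")
    }
    off <- as.integer(df$peak)
    if (any(off >= df$end - df$start)) {
      stop("peak line ", which(off >= df$end - df$start)[1],
           ": summit offset >= peak length")
    }
    summit <- ifelse(off < 0, (df$start + df$end) %/% 2L, df$start + off)
    return(peak_set(df$chrom, df$start, df$end, summit, df$signalValue, df$name))
  }
  if (ncol(df) < 6) stop("BED6 requires 6 columns")
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (any(df$start >= df$end)) {
    stop("peak line ", which(df$start >= df$end)[1], ": start >= end")
  }
  summit <- (df$start + df$end) %/% 2L
  peak_set(df$chrom, df$start, df$end, summit, df$score, df$name)
}

#' Write a peak set as narrowPeak
#'
#' The summit is emitted as an offset from `start`; strand is `.` and the
#' p/q-value columns are -1 (unset), per the ENCODE narrowPeak convention.
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  out <- data.frame(
    peaks$chrom, peaks$start, peaks$end, peaks$name, 0L, ".",
    peaks$signal, -1, -1, peaks$summit - peaks$start
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' Genes as rows (first column or row names), samples as columns. Every cell
#' must be numeric and nonnegative.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE, colClasses = "character")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(df)), nrow = nrow(df),
                               dimnames = list(rownames(df), colnames(df))))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at gene '", rownames(m)[idx[1]],
         "', sample '", colnames(m)[idx[2]], "'")
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative value at gene '", rownames(m)[idx[1]],
         "', sample '", colnames(m)[idx[2]], "'")
  }
  m
}

#' Construct a count matrix with sample groups
#'
#' @param values nonnegative numeric genes x samples matrix.
#' @param groups named character vector mapping every sample (column) to a
#'   condition label, e.g. control/kd.
#' @return list of class `count_matrix` with elements `values` and `groups`.
#' @export
count_matrix <- function(values, groups) {
  stopifnot(is.matrix(values))
  if (any(values < 0)) stop("counts must be nonnegative")
  if (is.null(colnames(values)) || is.null(rownames(values))) {
    stop("count matrix needs gene and sample names")
  }
  if (!all(colnames(values) %in% names(groups))) {
    stop("every sample needs a group label")
  }
  out <- list(values = values, groups = groups[colnames(values)])
  class(out) <- "count_matrix"
  out
}

#' Read a clinical table from TSV
#'
#' Columns: `sample_id`, `class` (tumor/normal), then optional `stage`
#' (tumors only), `time` and `event` (present together or not at all).
#'
#' @param path file path.
#' @return `data.frame` of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  clinical_table(df)
}

#' Validate and type a clinical data frame
#'
#' @param df data frame with at least `sample_id` and `class` columns.
#' @return `data.frame` of class `clinical_table`.
#' @export
clinical_table <- function(df) {
  if (!all(c("sample_id", "class") %in% names(df))) {
    stop("clinical table needs sample_id and class columns")
  }
  if (!all(df$class %in% c("tumor", "normal"))) stop("class must be tumor/normal")
  if (is.null(df$stage)) df$stage <- NA_character_
  if (is.null(df$time)) df$time <- NA_real_
  if (is.null(df$event)) df$event <- NA_integer_
  df$time <- as.numeric(df$time); df$event <- as.integer(df$event)
  if (any(xor(is.na(df$time), is.na(df$event)))) {
    stop("time and event must be present together")
  }
  if (any(!is.na(df$time) & df$time < 0)) stop("negative follow-up time")
  if (any(!is.na(df$event) & !df$event %in% c(0L, 1L))) stop("event must be 0/1")
  if (any(df$class == "normal" & !is.na(df$stage) & df$stage != "")) {
    stop("stage is only defined for tumor samples")
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Join an expression matrix with a clinical table
#'
#' Clinical rows whose sample is absent from the matrix (and matrix columns
#' without clinical annotation) are dropped with a warning naming them.
#'
#' @param m genes x samples matrix.
#' @param clinical a [clinical_table()].
#' @return list with the column-matched `matrix` and `clinical`.
#' @export
align_clinical <- function(m, clinical) {
  stopifnot(inherits(clinical, "clinical_table"))
  shared <- intersect(colnames(m), clinical$sample_id)
  lost_c <- setdiff(clinical$sample_id, shared)
  lost_m <- setdiff(colnames(m), shared)
  if (length(lost_c)) {
    warning("dropping clinical samples absent from matrix: ",
            paste(lost_c, collapse = ", "))
  }
  if (length(lost_m)) {
    warning("dropping matrix samples without clinical annotation: ",
            paste(lost_m, collapse = ", "))
  }
  if (!length(shared)) stop("no shared samples between matrix and clinical table")
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(cl) <- NULL
  list(matrix = m[, shared, drop = FALSE], clinical = cl)
}
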