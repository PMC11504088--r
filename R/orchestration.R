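#' Run the full integration pipeline
#'
#' Sequences every stage over one study: peak annotation and TSS-distance
#' summaries for both factors, TIP-style regulatory scores and their
#' combination, knockdown differential expression with deregulogram and
#' score-vs-fold-change trend, three-criterion signature selection, and the
#' clinomics evaluation (cohort normalization, metagene ROC overall and by
#' stage, Kaplan-Meier log-rank split). Inputs come either from a fixture
#' directory written by [simulate_all()] or from an in-memory simulation.
#'
#' When `out_dir` is given, per-stage tables are written as TSV/JSON together
#' with a reproducibility manifest (`manifest.json`) recording the package
#' version, parameters, input/output file digests and per-stage wall times.
#'
#' @param input a fixture directory path, or the list returned by
#'   [simulate_all()].
#' @param params list of analysis parameters; recognized entries:
#'   `window_bp`, `bin_bp`, `combine_mode`, `alpha`, `min_linear_fc`,
#'   `score_min`, `trend_window`.
#' @param out_dir optional output directory.
#' @return invisible list with all stage results (`annotation`, `scores`,
#'   `de`, `trend`, `panel`, `clinomics`, `manifest`).
#' @export
run_pipeline <- function(input, params = list(), out_dir = NULL) {
  p <- modifyList(list(
    window_bp = 100000L, bin_bp = 100L, combine_mode = "mean",
    alpha = 0.05, min_linear_fc = 1.25, score_min = 10, trend_window = 200L
  ), params)

  input_files <- character(0)
  if (is.character(input)) {
    if (!dir.exists(input)) stop("missing input directory: ", input)
    need <- c("genes.tsv", "tf1.narrowPeak", "tf2.narrowPeak",
              "counts_tf1.tsv", "counts_tf2.tsv", "groups_tf1.tsv",
              "groups_tf2.tsv", "cohort_tumor.tsv", "cohort_normal.tsv",
              "clinical.tsv")
    missing <- need[!file.exists(file.path(input, need))]
    if (length(missing)) stop("missing input file(s): ",
                              paste(missing, collapse = ", "))
    input_files <- file.path(input, need)
    sim <- .read_fixtures(input)
  } else {
    sim <- input
  }

  timings <- list()
  tic <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  biotype <- setNames(sim$genes$biotype, sim$genes$gene_id)

  annotation <- tic("annotate", {
    ann1 <- assign_peaks(sim$peaks_tf1, sim$genes)
    ann2 <- assign_peaks(sim$peaks_tf2, sim$genes)
    list(tf1 = ann1, tf2 = ann2,
         dist_tf1 = tss_distribution(ann1), dist_tf2 = tss_distribution(ann2))
  })

  scores <- tic("regscore", {
    pr1 <- build_tss_profile(sim$peaks_tf1, sim$genes, p$window_bp, p$bin_bp)
    pr2 <- build_tss_profile(sim$peaks_tf2, sim$genes, p$window_bp, p$bin_bp)
    s1 <- calibrate_scores(regulatory_scores(sim$genes, sim$peaks_tf1, pr1), "tf1")
    s2 <- calibrate_scores(regulatory_scores(sim$genes, sim$peaks_tf2, pr2), "tf2")
    list(profile_tf1 = pr1, profile_tf2 = pr2, tf1 = s1, tf2 = s2,
         combined = combine_tf_scores(s1, s2, p$combine_mode))
  })

  de <- tic("de", {
    de1 <- de_test(log_cpm(sim$counts_tf1), sim$counts_tf1$groups,
                   "control", "kd", biotype)
    de2 <- de_test(log_cpm(sim$counts_tf2), sim$counts_tf2$groups,
                   "control", "kd", biotype)
    list(tf1 = de1, tf2 = de2, deregulogram = deregulogram(de1, de2, p$alpha))
  })

  trend <- tic("trend", {
    sc <- setNames(scores$combined$combined, scores$combined$gene_id)
    fc <- setNames(de$tf1$log2fc, de$tf1$gene_id)
    score_fc_trend(sc, fc, p$trend_window)
  })

  panel <- tic("select", {
    suppressWarnings(select_signature(
      scores$combined, de$tf1, de$tf2, biotype,
      score_min = p$score_min, alpha = p$alpha,
      min_linear_fc = p$min_linear_fc
    ))
  })

  clin <- tic("clinomics", {
    zm <- cross_normalize(sim$cohort_tumor, sim$cohort_normal)
    cl <- sim$clinical[match(names(zm$class), sim$clinical$sample_id), ]
    up <- c(panel$coding_up, panel$noncoding_up)
    down <- c(panel$coding_down, panel$noncoding_down)
    res <- list(zmatrix = zm)
    for (side in c("up", "down")) {
      genes_side <- if (side == "up") up else down
      if (!length(intersect(genes_side, rownames(zm$z)))) next
      sc <- metagene_score(zm, genes_side)
      res[[paste0("roc_", side)]] <- roc_auc(sc, zm$class)
      res[[paste0("roc_by_stage_", side)]] <-
        roc_by_stage(sc, zm$class, setNames(cl$stage, cl$sample_id)[names(sc)])
      tum <- cl$class == "tumor" & !is.na(cl$time)
      if (sum(cl$event[tum], na.rm = TRUE) >= 2) {
        res[[paste0("km_", side)]] <- km_logrank(
          sc[cl$sample_id[tum]], cl$time[tum], cl$event[tum]
        )
      }
    }
    res
  })

  result <- list(annotation = annotation, scores = scores, de = de,
                 trend = trend, panel = panel, clinomics = clin)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) {
      write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      f
    }
    outs <- c(
      wt(annotation$dist_tf1, "tss_distribution_tf1.tsv"),
      wt(annotation$dist_tf2, "tss_distribution_tf2.tsv"),
      wt(scores$combined, "scores.tsv"),
      wt(de$tf1, "de_tf1.tsv"), wt(de$tf2, "de_tf2.tsv"),
      wt(trend, "trend.tsv"),
      wt(panel$provenance, "panel_provenance.tsv"),
      wt(panel_report(panel), "panel_report.tsv")
    )
    jsonlite::write_json(
      panel[c("coding_up", "coding_down", "noncoding_up", "noncoding_down")],
      file.path(out_dir, "panel.json")
    )
    outs <- c(outs, "panel.json")
    manifest <- list(
      version = as.character(packageVersion("regsig")),
      params = p,
      inputs = as.list(md5sum(input_files)),
      outputs = as.list(md5sum(file.path(out_dir, outs))),
      wall_time_s = as.list(timings)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
  }
  invisible(result)
}

.read_fixtures <- function(dir) {
  fp <- function(x) file.path(dir, x)
  read_cm <- function(k) {
    m <- read_matrix(fp(sprintf("counts_tf%d.tsv", k)))
    g <- read.delim(fp(sprintf("groups_tf%d.tsv", k)), stringsAsFactors = FALSE)
    count_matrix(m, setNames(g$group, g$sample_id))
  }
  list(
    genes = read_gene_models(fp("genes.tsv"), "tsv"),
    peaks_tf1 = read_peaks(fp("tf1.narrowPeak"), "narrowPeak"),
    peaks_tf2 = read_peaks(fp("tf2.narrowPeak"), "narrowPeak"),
    counts_tf1 = read_cm(1), counts_tf2 = read_cm(2),
    cohort_tumor = read_matrix(fp("cohort_tumor.tsv")),
    cohort_normal = read_matrix(fp("cohort_normal.tsv")),
    clinical = read_clinical(fp("clinical.tsv"))
  )
}
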