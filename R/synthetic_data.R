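#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: a reduced-scale
#' genome with one chromosome by default, a 70/30 coding/non-coding gene
#' universe, a set of planted direct targets carrying promoter peaks for both
#' factors, negative-binomial knockdown counts with concordant planted
#' effects, and a tumor/normal cohort in which planted genes are shifted and
#' survival hazard follows the planted up-signature's metagene score.
#'
#' @param seed integer seed that fully determines every output.
#' @param genome_length total genome length in bp.
#' @param n_genes number of genes.
#' @param frac_coding fraction of protein-coding genes.
#' @param n_planted number of planted direct-target genes.
#' @param frac_planted_up fraction of planted targets with upward knockdown
#'   response (default 0.75; the remainder respond downward).
#' @param promoter_signal_meanlog,promoter_signal_sdlog lognormal parameters
#'   of planted promoter-peak enrichment signal.
#' @param background_signal_meanlog,background_signal_sdlog lognormal
#'   parameters of background-peak signal.
#' @param background_peaks_per_mb background peak density per factor.
#' @param kd_fc_min,kd_fc_max planted |log2 fold change| range (uniform).
#' @param nb_dispersion negative-binomial dispersion of the counts.
#' @param n_per_arm RNA-seq replicates per condition arm.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of gene
#'   baseline mean counts (an expression-filtered universe).
#' @param n_tumor,n_normal cohort sizes.
#' @param tumor_shift_z tumor shift (in z units) of planted signature genes.
#' @param surv_beta log-hazard coefficient on the standardized metagene score.
#' @param surv_base_hazard baseline exponential hazard (per month).
#' @param censor_max upper bound of the uniform censoring time (months).
#' @param n_chrom number of chromosomes (genome split evenly).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, genome_length = 5e7, n_genes = 2000L,
                       frac_coding = 0.7, n_planted = 200L,
                       frac_planted_up = 0.75,
                       promoter_signal_meanlog = 2, promoter_signal_sdlog = 0.5,
                       background_signal_meanlog = 1,
                       background_signal_sdlog = 0.5,
                       background_peaks_per_mb = 5,
                       kd_fc_min = 0.5, kd_fc_max = 1.5,
                       nb_dispersion = 0.1, n_per_arm = 4L,
                       baseline_meanlog = 5.5, baseline_sdlog = 1.2,
                       n_tumor = 100L, n_normal = 50L, tumor_shift_z = 1.5,
                       surv_beta = 0.8, surv_base_hazard = log(2) / 24,
                       censor_max = 80, n_chrom = 1L) {
  cfg <- as.list(environment())
  num <- cfg[c("genome_length", "n_genes", "n_planted", "n_per_arm",
               "n_tumor", "n_normal", "background_peaks_per_mb",
               "nb_dispersion", "surv_base_hazard", "censor_max", "n_chrom")]
  if (any(unlist(num) <= 0)) stop("all rates and sizes must be positive")
  if (cfg$n_planted > cfg$n_genes) {
    stop("infeasible config: more planted targets than genes")
  }
  class(cfg) <- "sim_config"
  cfg
}

.sim_genes <- function(cfg) {
  n <- cfg$n_genes
  chrom_len <- cfg$genome_length / cfg$n_chrom
  chrom <- sprintf("chr%d", sample.int(cfg$n_chrom, n, replace = TRUE))
  len <- round(runif(n, 5e3, 5e4))
  start <- floor(runif(n, 0, chrom_len - len - 1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_cod <- round(cfg$frac_coding * n)
  bt <- c(rep("protein_coding", n_cod),
          sample(c("lincRNA", "pseudogene", "other_noncoding"), n - n_cod,
                 replace = TRUE, prob = c(0.5, 0.3, 0.2)))
  bt <- sample(bt)  # shuffle biotypes over gene ids
  gene_set(sprintf("g%04d", seq_len(n)), chrom, start, start + len, strand, bt)
}

.sim_peaks <- function(cfg, genes, planted, null) {
  chrom_len <- cfg$genome_length / cfg$n_chrom
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  n_bg <- round(cfg$genome_length / 1e6 * cfg$background_peaks_per_mb)
  bg_chrom <- sample(chroms, n_bg, replace = TRUE)
  bg_w <- round(runif(n_bg, 200, 500))
  bg_start <- floor(runif(n_bg, 0, chrom_len - bg_w - 1))
  bg_sig <- rlnorm(n_bg, cfg$background_signal_meanlog,
                   cfg$background_signal_sdlog)
  bg_off <- floor(bg_w / 2)
  chrom <- bg_chrom; start <- bg_start; width <- bg_w
  summit <- bg_start + bg_off; signal <- bg_sig
  if (!null && length(planted)) {
    gi <- match(planted, genes$gene_id)
    for (j in seq_along(gi)) {
      npk <- sample(1:2, 1)
      has_distal <- runif(1) < 0.3
      centers <- genes$tss[gi[j]] + round(runif(npk, -1000, 1000))
      if (has_distal) {
        centers <- c(centers, genes$tss[gi[j]] +
                       sample(c(-1, 1), 1) * round(runif(1, 1e4, 5e4)))
      }
      w <- round(runif(length(centers), 200, 400))
      st <- pmax(0L, pmin(as.integer(centers - w %/% 2),
                          as.integer(chrom_len - w - 1)))
      chrom <- c(chrom, rep(genes$chrom[gi[j]], length(centers)))
      start <- c(start, st)
      width <- c(width, w)
      summit <- c(summit, st + w %/% 2)
      signal <- c(signal, rlnorm(length(centers), cfg$promoter_signal_meanlog,
                                 cfg$promoter_signal_sdlog))
    }
  }
  o <- order(chrom, start)
  peak_set(chrom[o], start[o], (start + width)[o], summit[o], signal[o])
}

.sim_counts <- function(cfg, genes, mu, fc) {
  n <- cfg$n_genes; k <- cfg$n_per_arm
  ctrl <- matrix(rnbinom(n * k, mu = mu, size = 1 / cfg$nb_dispersion), n, k)
  kd <- matrix(rnbinom(n * k, mu = mu * 2^fc, size = 1 / cfg$nb_dispersion), n, k)
  m <- cbind(ctrl, kd)
  rownames(m) <- genes$gene_id
  colnames(m) <- c(sprintf("ctrl_%d", seq_len(k)), sprintf("kd_%d", seq_len(k)))
  count_matrix(m, setNames(rep(c("control", "kd"), each = k), colnames(m)))
}

#' Generate a complete synthetic study
#'
#' Draws gene models, two factors' peak sets (planted targets carry promoter
#' peaks for both factors within 1 kb of their TSS, plus occasional distal
#' peaks, over a uniform background), control/knockdown count matrices with
#' concordant planted effects, a tumor/normal cohort in which planted genes
#' are shifted by `tumor_shift_z` in the planted direction, and survival times
#' whose log hazard is `surv_beta` times the standardized planted-up metagene
#' score. Everything is determined by `config$seed`. A truth ledger records
#' every planted effect.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, all fixtures are written as
#'   plain-text files (`genes.tsv`, `tf1.narrowPeak`, `tf2.narrowPeak`,
#'   `counts_tf*.tsv`, `groups_tf*.tsv`, `cohort_*.tsv`, `clinical.tsv`,
#'   `truth.json`).
#' @param null when `TRUE`, all planted effects are removed (no promoter
#'   peaks, zero fold changes and shifts, zero hazard coefficient) for
#'   type-I-error suites.
#' @return invisible list with `genes`, `peaks_tf1`, `peaks_tf2`,
#'   `counts_tf1`, `counts_tf2`, `cohort_tumor`, `cohort_normal`, `clinical`,
#'   `truth`.
#' @export
simulate_all <- function(config = sim_config(), dir = NULL, null = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- .sim_genes(config)
  planted <- sort(sample(genes$gene_id, config$n_planted))
  direction <- ifelse(runif(config$n_planted) < config$frac_planted_up, 1, -1)
  if (null) direction <- rep(0, config$n_planted)
  fc1 <- direction * runif(config$n_planted, config$kd_fc_min, config$kd_fc_max)
  fc2 <- direction * runif(config$n_planted, config$kd_fc_min, config$kd_fc_max)
  if (null) fc1 <- fc2 <- rep(0, config$n_planted)

  peaks1 <- .sim_peaks(config, genes, planted, null)
  peaks2 <- .sim_peaks(config, genes, planted, null)

  mu <- rlnorm(config$n_genes, config$baseline_meanlog, config$baseline_sdlog)
  fcv1 <- fcv2 <- setNames(rep(0, config$n_genes), genes$gene_id)
  fcv1[planted] <- fc1; fcv2[planted] <- fc2
  counts1 <- .sim_counts(config, genes, mu, fcv1)
  counts2 <- .sim_counts(config, genes, mu, fcv2)

  # cohort on log2 scale: planted genes shifted in tumors by tumor_shift_z
  shift <- setNames(rep(0, config$n_genes), genes$gene_id)
  if (!null) shift[planted] <- config$tumor_shift_z * direction
  base_expr <- rnorm(config$n_genes, 6, 1.5)
  nt <- config$n_tumor; nn <- config$n_normal
  lt <- base_expr + shift + matrix(rnorm(config$n_genes * nt), config$n_genes)
  ln <- base_expr + matrix(rnorm(config$n_genes * nn), config$n_genes)
  dimnames(lt) <- list(genes$gene_id, sprintf("tumor_%03d", seq_len(nt)))
  dimnames(ln) <- list(genes$gene_id, sprintf("normal_%03d", seq_len(nn)))
  cohort_tumor <- round(2^lt, 3)
  cohort_normal <- round(2^ln, 3)

  up_genes <- planted[direction > 0]
  beta <- if (null) 0 else config$surv_beta
  if (length(up_genes) >= 1) {
    zs <- (lt - rowMeans(lt)) / apply(lt, 1, sd)
    score <- colMeans(zs[up_genes, , drop = FALSE])
    score <- (score - mean(score)) / sd(score)
  } else {
    score <- rnorm(nt)
  }
  hazard <- config$surv_base_hazard * exp(beta * score)
  t_ev <- rexp(nt, rate = hazard)
  cens <- runif(nt, 0, config$censor_max)
  clinical <- clinical_table(data.frame(
    sample_id = c(colnames(cohort_tumor), colnames(cohort_normal)),
    class = rep(c("tumor", "normal"), c(nt, nn)),
    stage = c(sample(c("I", "II", "III", "IV"), nt, replace = TRUE),
              rep(NA_character_, nn)),
    time = c(pmin(t_ev, cens), rep(NA_real_, nn)),
    event = c(as.integer(t_ev <= cens), rep(NA_integer_, nn)),
    stringsAsFactors = FALSE
  ))

  truth <- list(
    seed = config$seed, null = null,
    planted = data.frame(
      gene_id = planted,
      direction = ifelse(direction > 0, "up", ifelse(direction < 0, "down", "none")),
      fc_tf1 = fc1, fc_tf2 = fc2,
      cohort_shift = as.numeric(shift[planted]),
      stringsAsFactors = FALSE
    ),
    surv_beta = beta
  )

  out <- list(
    genes = genes, peaks_tf1 = peaks1, peaks_tf2 = peaks2,
    counts_tf1 = counts1, counts_tf2 = counts2,
    cohort_tumor = cohort_tumor, cohort_normal = cohort_normal,
    clinical = clinical, truth = truth
  )
  if (!is.null(dir)) .write_fixtures(out, dir)
  invisible(out)
}

#' Generate a null study (no planted effects)
#'
#' Identical to [simulate_all()] with every effect removed: background-only
#' peaks, zero fold changes, unshifted cohort, score-independent survival.
#'
#' @inheritParams simulate_all
#' @export
simulate_null <- function(config = sim_config(), dir = NULL) {
  simulate_all(config, dir = dir, null = TRUE)
}

.write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_fixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_gene_models(sim$genes, fp("genes.tsv"))
  write_peaks(sim$peaks_tf1, fp("tf1.narrowPeak"))
  write_peaks(sim$peaks_tf2, fp("tf2.narrowPeak"))
  .write_matrix_tsv(sim$counts_tf1$values, fp("counts_tf1.tsv"))
  .write_matrix_tsv(sim$counts_tf2$values, fp("counts_tf2.tsv"))
  for (k in 1:2) {
    cm <- sim[[paste0("counts_tf", k)]]
    write.table(
      data.frame(sample_id = names(cm$groups), group = unname(cm$groups)),
      fp(sprintf("groups_tf%d.tsv", k)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  .write_matrix_tsv(sim$cohort_tumor, fp("cohort_tumor.tsv"))
  .write_matrix_tsv(sim$cohort_normal, fp("cohort_normal.tsv"))
  write.table(sim$clinical, fp("clinical.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(sim$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}
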