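#' Cross-normalize tumor and normal expression matrices
#'
#' Takes the gene intersection of the two cohorts, scales every sample so its
#' upper quartile equals a fixed target (making each sample's profile
#' invariant to global scaling), log2(x+1)-transforms, and standardizes each
#' gene to mean 0 / sd 1 over the pooled cohort. Genes with zero pooled
#' variance are dropped with a message; samples whose upper quartile is zero
#' are dropped with a warning. With `method = "quantile"` the per-sample step
#' is quantile normalization (via limma) instead of upper-quartile scaling.
#'
#' @param tumor_matrix,normal_matrix genes x samples matrices of nonnegative
#'   expression values.
#' @param method `"uq"` (default) or `"quantile"`.
#' @param target upper-quartile target for `"uq"` (default 1000).
#' @return object of class `z_matrix`: list with `z` (genes x samples) and
#'   `class` (named `"tumor"`/`"normal"` per sample).
#' @export
cross_normalize <- function(tumor_matrix, normal_matrix,
                            method = c("uq", "quantile"), target = 1000) {
  method <- match.arg(method)
  shared <- intersect(rownames(tumor_matrix), rownames(normal_matrix))
  if (!length(shared)) stop("no shared genes between cohorts")
  lost <- length(union(rownames(tumor_matrix), rownames(normal_matrix))) -
    length(shared)
  if (lost) message(lost, " gene(s) outside the cohort intersection dropped")
  pooled <- cbind(tumor_matrix[shared, , drop = FALSE],
                  normal_matrix[shared, , drop = FALSE])
  cls <- setNames(rep(c("tumor", "normal"),
                      c(ncol(tumor_matrix), ncol(normal_matrix))),
                  colnames(pooled))
  if (method == "uq") {
    uq <- apply(pooled, 2, quantile, probs = 0.75, names = FALSE)
    if (any(uq == 0)) {
      warning("dropping sample(s) with zero upper quartile: ",
              paste(colnames(pooled)[uq == 0], collapse = ", "))
      pooled <- pooled[, uq > 0, drop = FALSE]
      cls <- cls[colnames(pooled)]
      uq <- uq[uq > 0]
    }
    scaled <- sweep(pooled, 2, target / uq, "*")
  } else {
    if (!requireNamespace("limma", quietly = TRUE)) {
      stop("quantile normalization requires the limma package")
    }
    scaled <- limma::normalizeQuantiles(pooled)
  }
  lg <- log2(scaled + 1)
  mu <- rowMeans(lg)
  s <- apply(lg, 1, sd)
  if (any(s == 0)) {
    message(sum(s == 0), " zero-variance gene(s) dropped during z-scoring")
  }
  keep <- s > 0
  z <- (lg[keep, , drop = FALSE] - mu[keep]) / s[keep]
  out <- list(z = z, class = cls)
  class(out) <- "z_matrix"
  out
}

#' Per-sample metagene score
#'
#' The mean standardized expression of a gene panel per sample; a one-gene
#' panel reduces to that gene's z-score. Panel members absent from the matrix
#' are reported via `message()`; an entirely absent panel is an error.
#'
#' @param zmatrix a [cross_normalize()] result (or plain z matrix).
#' @param gene_list character vector of panel gene ids.
#' @return named numeric vector, one score per sample.
#' @export
metagene_score <- function(zmatrix, gene_list) {
  z <- if (inherits(zmatrix, "z_matrix")) zmatrix$z else zmatrix
  present <- intersect(gene_list, rownames(z))
  if (!length(present)) stop("no panel gene present in the matrix")
  if (length(present) < length(gene_list)) {
    message(length(gene_list) - length(present),
            " panel gene(s) absent from the matrix")
  }
  colMeans(z[present, , drop = FALSE])
}

#' ROC analysis of a score against binary class labels
#'
#' AUC by Mann-Whitney pair counting (ties count 1/2), 95% confidence interval
#' by the Hanley-McNeil normal approximation, and sensitivity/specificity at
#' the Youden-optimal cut (`score >= cutoff` predicts the positive class).
#'
#' @param scores numeric vector.
#' @param labels vector of class labels aligned with `scores`.
#' @param positive label of the positive class (default `"tumor"`).
#' @return object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `sensitivity`, `specificity`, `cutoff`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = "tumor") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  cuts <- sort(unique(scores))
  best <- c(youden = -Inf, sens = NA, spec = NA, cut = NA)
  for (cut in cuts) {
    sens <- sum(scores >= cut & pos) / n1
    spec <- sum(scores < cut & !pos) / n0
    if (sens + spec - 1 > best["youden"]) {
      best <- c(youden = sens + spec - 1, sens = sens, spec = spec, cut = cut)
    }
  }
  out <- list(
    auc = auc,
    ci_low = max(0, auc - qnorm(0.975) * se),
    ci_high = min(1, auc + qnorm(0.975) * se),
    sensitivity = unname(best["sens"]), specificity = unname(best["spec"]),
    cutoff = unname(best["cut"]), n_pos = n1, n_neg = n0
  )
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), sens %.2f / spec %.2f at cut %.3g (n+ %d, n- %d)\n",
              x$auc, x$ci_low, x$ci_high, x$sensitivity, x$specificity,
              x$cutoff, x$n_pos, x$n_neg))
  invisible(x)
}

#' Stagewise ROC: each tumor stage against all normals
#'
#' Runs [roc_auc()] once per tumor stage (that stage's tumors vs every normal
#' sample) plus the pooled contrast. Stages with fewer than 3 tumors are
#' skipped with a warning. Both `auc` and `1 - auc` are reported so panels of
#' downregulated genes (AUC < 0.5) can be read on either side.
#'
#' @param scores named numeric vector over all samples.
#' @param labels tumor/normal labels aligned with `scores`.
#' @param stages stage label per sample (NA for normals).
#' @return `data.frame` with one row per stage plus `"pooled"`; columns
#'   include `auc`, `auc_flipped`, CI bounds and class sizes.
#' @export
roc_by_stage <- function(scores, labels, stages) {
  norm_idx <- labels == "normal"
  res <- list()
  row_of <- function(name, roc) {
    data.frame(stage = name, auc = roc$auc, auc_flipped = 1 - roc$auc,
               ci_low = roc$ci_low, ci_high = roc$ci_high,
               n_pos = roc$n_pos, n_neg = roc$n_neg,
               stringsAsFactors = FALSE)
  }
  for (st in sort(unique(stages[labels == "tumor" & !is.na(stages)]))) {
    idx <- (labels == "tumor" & !is.na(stages) & stages == st) | norm_idx
    if (sum(labels[idx] == "tumor") < 3) {
      warning("stage ", st, " has fewer than 3 tumors; skipped")
      next
    }
    res[[st]] <- row_of(st, roc_auc(scores[idx], labels[idx]))
  }
  res[["pooled"]] <- row_of("pooled", roc_auc(scores, labels))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier comparison of high vs low metagene score
#'
#' Dichotomizes tumors at the given split (default: median score, ties to the
#' low group), computes the log-rank test over pooled event times and emits
#' Kaplan-Meier curves as step-function tables.
#'
#' @param scores numeric score per tumor sample.
#' @param time follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param split `"median"` or a numeric cutoff; `score > cutoff` is "high".
#' @return object of class `survival_comparison`: `logrank_chi2`, `p`,
#'   `n_high`, `n_low`, `direction` (group with worse survival), and `km`
#'   (`data.frame` step table with `group`, `time`, `n_risk`, `n_event`,
#'   `surv`).
#' @export
km_logrank <- function(scores, time, event, split = "median") {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  if (sum(event) < 2) stop("need at least 2 events")
  cut <- if (identical(split, "median")) median(scores) else as.numeric(split)
  grp <- factor(ifelse(scores > cut, "high", "low"), levels = c("low", "high"))
  if (any(table(grp) == 0)) stop("median split leaves one group empty")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi2 <- unname(sd_fit$chisq)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  # the group observing more events than expected fares worse
  worse <- c("low", "high")[which.max(sd_fit$obs - sd_fit$exp)]
  sf <- survival::survfit(survival::Surv(time, event) ~ grp)
  km <- data.frame(
    group = rep(sub("^grp=", "", names(sf$strata)), sf$strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event, surv = sf$surv,
    stringsAsFactors = FALSE
  )
  out <- list(
    logrank_chi2 = chi2, p = p,
    n_high = sum(grp == "high"), n_low = sum(grp == "low"),
    direction = worse, cutoff = cut, km = km
  )
  class(out) <- "survival_comparison"
  out
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("log-rank chi2 %.3f, p %.3g (%d high vs %d low; worse survival: %s)\n",
              x$logrank_chi2, x$p, x$n_high, x$n_low, x$direction))
  invisible(x)
}

#' Compare metagene scores across strata
#'
#' Kruskal-Wallis omnibus test plus BH-adjusted pairwise Wilcoxon rank-sum
#' tests between strata.
#'
#' @param scores numeric scores.
#' @param strata stratum label per sample; every stratum needs >= 2 samples.
#' @return list with `H`, `p`, `pairwise` (matrix of BH-adjusted p-values).
#' @export
strata_compare <- function(scores, strata) {
  strata <- factor(strata)
  sizes <- table(strata)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need at least 2 strata with at least 2 samples each")
  }
  kw <- kruskal.test(scores, strata)
  pw <- suppressWarnings(
    pairwise.wilcox.test(scores, strata, p.adjust.method = "BH")
  )
  list(H = unname(kw$statistic), p = kw$p.value, pairwise = pw$p.value)
}

#' Metagene panel behaviour across multiple cohorts
#'
#' For each cohort: cross-normalize tumor vs normal, score the panel, test the
#' tumor/normal score difference with a two-sided Wilcoxon rank-sum test and
#' call the direction from the median difference. P-values are BH-adjusted
#' across cohorts. Cohorts missing a class are skipped with a warning.
#'
#' @param cohorts named list; each element a list with `tumor` and `normal`
#'   genes x samples matrices.
#' @param panel character vector of panel gene ids.
#' @return `data.frame` with per-cohort `direction`, `p`, `q`, `significant`.
#' @export
multicancer_panel <- function(cohorts, panel) {
  if (length(cohorts) < 2) stop("need at least 2 cohorts")
  rows <- list()
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    if (is.null(co$tumor) || is.null(co$normal) ||
        ncol(co$tumor) == 0 || ncol(co$normal) == 0) {
      warning("cohort ", nm, " is missing a class; skipped")
      next
    }
    zm <- cross_normalize(co$tumor, co$normal)
    sc <- metagene_score(zm, panel)
    st <- sc[zm$class == "tumor"]; sn <- sc[zm$class == "normal"]
    wt <- suppressWarnings(wilcox.test(st, sn))
    rows[[nm]] <- data.frame(
      cohort = nm,
      direction = if (median(st) >= median(sn)) "up" else "down",
      p = wt$p.value, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q <= 0.05
  out
}
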