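#!/usr/bin/env Rscript
# Stage 4: knockdown transcriptomes. Gene-wise Welch tests on log-CPM for
# both knockdowns, DEG classification, cross-knockdown overlap and
# deregulogram, and the regulatory-score-vs-fold-change trend.

suppressPackageStartupMessages(library(regsig))

fixture_dir <- "results/fixtures"
genes <- read_gene_models(file.path(fixture_dir, "genes.tsv"), "tsv")
biotype <- setNames(genes$biotype, genes$gene_id)

de <- list()
for (tf in c("tf1", "tf2")) {
  m <- read_matrix(file.path(fixture_dir, sprintf("counts_%s.tsv", tf)))
  grp <- read.delim(file.path(fixture_dir, sprintf("groups_%s.tsv", tf)))
  cm <- count_matrix(m, setNames(grp$group, grp$sample_id))
  de[[tf]] <- de_test(log_cpm(cm), cm$groups, "control", "kd", biotype)
  cls <- classify_degs(de[[tf]])
  cat(sprintf("%s knockdown: %d up, %d down of %d genes (FDR 0.05, FC 1.25)\n",
              tf, sum(cls == "up"), sum(cls == "down"), length(cls)))
  write.table(de[[tf]], sprintf("results/de_%s.tsv", tf), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

ov <- overlap_degs(classify_degs(de$tf1), classify_degs(de$tf2), biotype)
write.table(ov, "results/common_degs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("commonly affected genes (same direction in both knockdowns):\n")
print(ov)

dg <- deregulogram(de$tf1, de$tf2)
write.table(dg$records, "results/deregulogram.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("deregulogram: r = %.2f, %.0f%% concordant over %d doubly significant genes\n",
            dg$summary$r, dg$summary$pct_concordant, dg$summary$n_both))

combined <- read.delim("results/scores.tsv")
sc <- setNames(combined$combined, combined$gene_id)
tr <- score_fc_trend(sc, setNames(de$tf1$log2fc, de$tf1$gene_id))
write.table(tr, "results/trend.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
n <- nrow(tr); dec <- n %/% 10
cat(sprintf("trend: mean fold change %.2f in the top score decile vs %.2f in the bottom\n",
            mean(tr$trend[(n - dec + 1):n]), mean(tr$trend[1:dec])))
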