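#!/usr/bin/env Rscript
# Stage 3: TIP-style regulatory scores. Learn each factor's average binding
# profile around the TSS, score every gene, calibrate so the median positive
# score maps to 10, and combine the two factors.

suppressPackageStartupMessages(library(regsig))

fixture_dir <- "results/fixtures"
genes <- read_gene_models(file.path(fixture_dir, "genes.tsv"), "tsv")

scores <- list()
for (tf in c("tf1", "tf2")) {
  peaks <- read_peaks(file.path(fixture_dir, paste0(tf, ".narrowPeak")),
                      "narrowPeak")
  prof <- build_tss_profile(peaks, genes)
  inner <- sum(prof$weights[abs(prof$offsets) <= 2000])
  raw <- regulatory_scores(genes, peaks, prof)
  scores[[tf]] <- calibrate_scores(raw, tf)
  cat(sprintf("%s: %.0f%% of profile weight within 2 kb of the TSS; %d genes score >= 10\n",
              tf, 100 * inner, sum(scores[[tf]]$scaled >= 10)))
}

combined <- combine_tf_scores(scores$tf1, scores$tf2, "mean")
write.table(combined, "results/scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("combined: %d / %d genes with mean scaled score >= 10\n",
            sum(combined$combined >= 10), nrow(combined)))
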