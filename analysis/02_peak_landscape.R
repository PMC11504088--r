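#!/usr/bin/env Rscript
# Stage 2: where does each factor bind? Nearest-TSS annotation, distance
# distributions, territory-normalized enrichment, and co-occurrence of the
# two factors' peak sets by relative distance.

suppressPackageStartupMessages(library(regsig))

fixture_dir <- "results/fixtures"
out <- "results"
genes <- read_gene_models(file.path(fixture_dir, "genes.tsv"), "tsv")
cfg_L <- 5e7  # genome length used by stage 1

for (tf in c("tf1", "tf2")) {
  peaks <- read_peaks(file.path(fixture_dir, paste0(tf, ".narrowPeak")),
                      "narrowPeak")
  ann <- assign_peaks(peaks, genes)
  dist <- tss_distribution(ann)
  enr <- annotation_enrichment(ann, genes, cfg_L)
  write.table(ann, file.path(out, paste0("annotation_", tf, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dist, file.path(out, paste0("tss_distribution_", tf, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(enr, file.path(out, paste0("enrichment_", tf, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d peaks, %.1f%% within 5 kb of a TSS; 0-1 kb enrichment %.1fx\n",
              tf, nrow(ann), sum(dist$pct[1:3]),
              enr$ratio[enr$category == "prom_0_1kb"]))
}

p1 <- read_peaks(file.path(fixture_dir, "tf1.narrowPeak"), "narrowPeak")
p2 <- read_peaks(file.path(fixture_dir, "tf2.narrowPeak"), "narrowPeak")
rd <- reldist(p1, p2)
write.table(rd$hist, file.path(out, "reldist_tf1_tf2.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("reldist factor1 vs factor2: %d comparisons, %.0f%% below 0.1 (uniform expects 20%%)\n",
            length(rd$rel), 100 * mean(rd$rel < 0.1)))
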