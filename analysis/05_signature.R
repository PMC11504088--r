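#!/usr/bin/env Rscript
# Stage 5: three-criterion signature selection. Genes need a combined
# regulatory score >= 10 and a significant, unidirectional fold change of at
# least 1.25 in both knockdowns; admitted genes split into four signatures
# by direction and coding/non-coding biotype.

suppressPackageStartupMessages(library(regsig))

genes <- read_gene_models("results/fixtures/genes.tsv", "tsv")
biotype <- setNames(genes$biotype, genes$gene_id)
combined <- read.delim("results/scores.tsv")
de1 <- read.delim("results/de_tf1.tsv")
de2 <- read.delim("results/de_tf2.tsv")

panel <- suppressWarnings(select_signature(
  setNames(combined$combined, combined$gene_id), de1, de2, biotype
))
rep_ <- panel_report(panel)
write.table(panel$provenance, "results/panel_provenance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rep_, "results/panel_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(
  panel[c("coding_up", "coding_down", "noncoding_up", "noncoding_down")],
  "results/panel.json"
)

print(panel)
if (rep_$total > 0) {
  cat(sprintf("%.0f%% of admitted genes are upregulated\n", rep_$pct_up))
} else {
  cat("no gene passed all three criteria at these knockdown sample sizes;\n")
  cat("see the methods vignette for the power analysis of this regime\n")
}
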