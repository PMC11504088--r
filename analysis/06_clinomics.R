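#!/usr/bin/env Rscript
# Stage 6: clinomics. Cross-normalize the tumor/normal cohort, score the
# planted signatures, and evaluate diagnosis (ROC overall and per stage),
# prognosis (median-split Kaplan-Meier log-rank) and stratum effects.
# The planted (truth) signatures are used so this stage is informative even
# when stage 5 admits no genes at the knockdown power available.

suppressPackageStartupMessages(library(regsig))

fixture_dir <- "results/fixtures"
tumor <- read_matrix(file.path(fixture_dir, "cohort_tumor.tsv"))
normal <- read_matrix(file.path(fixture_dir, "cohort_normal.tsv"))
clinical <- read_clinical(file.path(fixture_dir, "clinical.tsv"))
truth <- jsonlite::read_json(file.path(fixture_dir, "truth.json"),
                             simplifyVector = TRUE)
panel <- jsonlite::read_json("results/panel.json", simplifyVector = TRUE)

zm <- suppressMessages(cross_normalize(tumor, normal))
cl <- clinical[match(names(zm$class), clinical$sample_id), ]

sigs <- list(
  planted_up = truth$planted$gene_id[truth$planted$direction == "up"],
  planted_down = truth$planted$gene_id[truth$planted$direction == "down"]
)
sel_up <- unlist(panel[c("coding_up", "noncoding_up")], use.names = FALSE)
if (length(sel_up)) sigs$selected_up <- sel_up

roc_rows <- list()
for (nm in names(sigs)) {
  sc <- metagene_score(zm, sigs[[nm]])
  roc <- roc_auc(sc, zm$class)
  cat(sprintf("%s (%d genes): ", nm, length(sigs[[nm]]))); print(roc)
  stage_tab <- roc_by_stage(sc, zm$class, setNames(cl$stage, cl$sample_id))
  stage_tab$signature <- nm
  roc_rows[[nm]] <- stage_tab

  tum <- cl$class == "tumor"
  km <- km_logrank(sc[cl$sample_id[tum]], cl$time[tum], cl$event[tum])
  cat("  survival: "); print(km)
  write.table(km$km, sprintf("results/km_%s.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)

  strat <- strata_compare(sc[cl$sample_id[tum]], cl$stage[tum])
  cat(sprintf("  stage strata: Kruskal-Wallis H = %.2f, p = %.3g\n",
              strat$H, strat$p))
}
write.table(do.call(rbind, roc_rows), "results/roc_by_stage.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# multi-cohort panel: this study's cohort plus two effect-free cohorts drawn
# from null simulations, mimicking unrelated cancer types
null1 <- simulate_null(sim_config(seed = 4301, n_tumor = 60, n_normal = 30))
null2 <- simulate_null(sim_config(seed = 4302, n_tumor = 60, n_normal = 30))
cohorts <- list(
  gastric_like = list(tumor = tumor, normal = normal),
  null_cohort_a = list(tumor = null1$cohort_tumor, normal = null1$cohort_normal),
  null_cohort_b = list(tumor = null2$cohort_tumor, normal = null2$cohort_normal)
)
mc <- suppressMessages(multicancer_panel(cohorts, sigs$planted_up))
write.table(mc, "results/multicancer.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("multi-cohort panel (planted up-signature):\n")
print(mc)
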