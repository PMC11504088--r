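#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study the rest of the analysis consumes.
# Emulates two factors' ChIP-seq peak sets, control/knockdown RNA-seq counts,
# and a tumor/normal cohort with clinical annotation, at reduced desk scale.

suppressPackageStartupMessages(library(regsig))

fixture_dir <- "results/fixtures"
cfg <- sim_config(seed = 42)
sim <- simulate_all(cfg, dir = fixture_dir)

cat("Simulated study written to", fixture_dir, "\n")
cat(sprintf("  genes: %d (%.0f%% coding), genome %.0f Mb\n",
            nrow(sim$genes),
            100 * mean(sim$genes$biotype == "protein_coding"),
            cfg$genome_length / 1e6))
cat(sprintf("  peaks: %d (factor 1) / %d (factor 2)\n",
            nrow(sim$peaks_tf1), nrow(sim$peaks_tf2)))
cat(sprintf("  planted direct targets: %d (%d up, %d down)\n",
            nrow(sim$truth$planted),
            sum(sim$truth$planted$direction == "up"),
            sum(sim$truth$planted$direction == "down")))
cat(sprintf("  knockdown arms: %d vs %d replicates, NB dispersion %.2f\n",
            cfg$n_per_arm, cfg$n_per_arm, cfg$nb_dispersion))
cat(sprintf("  cohort: %d tumors / %d normals, planted shift %.1f z\n",
            cfg$n_tumor, cfg$n_normal, cfg$tumor_shift_z))
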