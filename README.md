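# regsig

Integration of transcription-factor ChIP-seq binding with knockdown RNA-seq
differential expression to nominate direct target genes, and evaluation of
compact coding/non-coding *metagene signatures* built from those targets on
tumor/normal expression cohorts — diagnostically (ROC AUC, overall and per
tumor stage) and prognostically (median-split Kaplan–Meier log-rank).

The package is aimed at regulatory-genomics analyses of lineage-survival
transcription factors (the motivating case is a pair of GATA-family factors
in gastric cancer cells): you have peak calls for one or two factors,
control-vs-knockdown count matrices, and a clinical expression cohort, and
you want a tested, deterministic path from those inputs to annotated
binding landscapes, per-gene regulatory scores, selected signatures, and
clinical performance numbers.

## The core quantities

* **TIP-style regulatory score.** With $w(d)$ the smoothed, normalized
  genome-wide average binding profile at strand-oriented offset $d$ from
  the TSS (window ±100 kb, bin 100 bp), a gene's raw score is
  $s_g = \sum_d w(d)\,x_g(d)$, where $x_g(d)$ sums the signal of peaks
  covering that offset. Scores are z-normalized and calibrated so the
  median strictly-positive raw score maps to 10; the two factors' scaled
  scores are combined (mean by default).
* **Three-criterion selection.** A gene enters the signature panel iff
  (i) combined score ≥ 10, (ii) both knockdowns deregulate it significantly
  in the same direction (BH FDR ≤ 0.05), and (iii) with linear fold change
  ≥ 1.25 in both. Panels split by direction × coding/non-coding into four
  signatures.
* **Clinomics.** Cohorts are upper-quartile cross-normalized, log2
  transformed and gene-wise z-scored; a metagene score is the mean z over
  panel genes; AUC is Mann–Whitney pair counting with Hanley–McNeil
  intervals; survival uses the log-rank test at a median score split.

A first-class synthetic-data module (`simulate_all()` / `simulate_null()`)
generates every input at reduced scale from one seed, with a truth ledger,
so the whole pipeline is exercised and tested without downloads.

## Worked example

The `analysis/` scripts run the full study on a simulated dataset
(`Rscript analysis/01_simulate.R` through `06_clinomics.R`, writing tables
under `results/`). In miniature:

```r
library(regsig)
sim <- simulate_all(sim_config(seed = 42))

ann <- assign_peaks(sim$peaks_tf1, sim$genes)
head(tss_distribution(ann), 3)
#>     category count       pct
#> 1 prom_0_1kb   325 52.759740
#> 2 prom_1_3kb    46  7.467532
#> 3 prom_3_5kb    36  5.844156

prof <- build_tss_profile(sim$peaks_tf1, sim$genes)
scores <- calibrate_scores(regulatory_scores(sim$genes, sim$peaks_tf1, prof), "tf1")
sum(scores$scaled >= 10)   # genes at or above the positive-score median
#> [1] 846

zm <- cross_normalize(sim$cohort_tumor, sim$cohort_normal)
up <- sim$truth$planted$gene_id[sim$truth$planted$direction == "up"]
roc_auc(metagene_score(zm, up), zm$class)
#> AUC 1.000 (95% CI 1.000-1.000), sens 1.00 / spec 1.00 at cut 0.183 (n+ 100, n- 50)

cl <- sim$clinical[sim$clinical$class == "tumor", ]
km_logrank(metagene_score(zm, up)[cl$sample_id], cl$time, cl$event)
#> log-rank chi2 13.790, p 0.000204 (50 high vs 50 low; worse survival: high)
```

52.8% of this factor's peaks sit within 1 kb of a TSS (the generator plants
promoter peaks at its 200 direct targets over a uniform background); the
planted upregulated signature separates the 100 simulated tumors from the
50 normals perfectly and its high-scoring half of tumors has significantly
worse survival, as planted. Note that on this same fixture the *selection*
stage admits few or no genes: with negative-binomial dispersion 0.1 and 4
replicates per arm, the per-gene knockdown tests are underpowered for
0.5–1.5 log2-unit effects — see the methods vignette
(`vignettes/regsig-methods.Rmd`) for the power analysis.

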