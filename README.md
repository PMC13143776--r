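# nelfayap

Analysis toolkit for studying how the NELF-mediated promoter-proximal
pausing (PPP) checkpoint constrains YAP-driven transcription, and what
the joint YAP/NELFA status of a breast tumor means clinically.

YAP, the Hippo-pathway effector, drives oncogenic transcriptional
programs (proliferation, EMT, TGF-beta signaling), most aggressively in
triple-negative breast cancer.  The NELF complex stabilizes RNA
polymerase II pausing just downstream of the transcription start site.
This package provides the quantitative machinery used to dissect their
interplay from a four-condition siRNA design (siControl, siNELFA,
siYAP, siNELFA+siYAP) through to patient survival:

* **Differential expression** — a minimal, calibrated per-contrast
  stage (median-of-ratios normalization, pseudocounted log2 fold
  changes, Wald test with a method-of-moments negative-binomial
  variance and a small-sample t reference).
* **Co-regulation classification** — each gene is assigned to one of
  four mutually exclusive categories from its three knockdown fold
  changes $(f_N, f_Y, f_D)$: NELFA-suppressed/YAP-activated
  ($f_N \ge +1$, $f_Y \le -1$, $-1 < f_D < +1$), the mirror category,
  co-suppressed ($f_N, f_Y \ge +1$, $f_D \ge \max(f_N, f_Y)$) and
  co-activated (mirror), gated on significance in both single
  knockdowns; plus exact Venn/UpSet region counts for DEG overlaps.
* **Enrichment** — preranked GSEA (weighted Kolmogorov–Smirnov running
  sum, gene-sampling null, NES, +1-smoothed nominal p) and
  Fisher-exact TF-target overlap (one-sided p, $ad/bc$ odds ratio with
  Haldane correction).
* **Promoter-proximal pausing** — promoter (TSS ± 150 bp) and
  strand-directional gene-body (TSS+250..+2250) windows on the longest
  transcript, log2(ChIP/Input) occupancy with a 0.5 retention
  threshold, strand-combined nascent output, and a coordinated-loss
  caller (`coordinated_loss_up` / `output_down` / `unchanged` /
  `not_retained`).
* **Clinical stratification** — composite IHC scores (binned percent ×
  intensity), ROC/Youden dichotomization, Kaplan–Meier curves,
  Mantel–Cox log-rank tests, uncorrected Pearson chi-square
  contingency analysis, median splits, and joint YAP×NELFA four-group
  stratification.
* **Synthetic data with truth tables** — negative-binomial counts with
  planted category effects, noiseless promoter-peaked tracks with
  planted occupancy loss, and survival cohorts with group-specific
  hazards, so every stage is testable offline.

## Worked example

```r
library(nelfayap)

# simulate the four-arm knockdown design with 50 planted genes per category
sim  <- simulate_counts(n_genes = 1200, n_planted_per_category = 50, seed = 101)
tab  <- contrast_table(sim$counts)
calls <- classify_all(tab, alpha = 0.05)
table(calls$category)
#> NELFA_suppressed_YAP_activated NELFA_activated_YAP_suppressed
#>                             49                             50
#>                  co_suppressed                   co_activated
#>                             49                             45
#>                           none
#>                           1007
planted <- sim$truth$category != "none"
mean(calls$category[planted] == sim$truth$category[planted])
#> [1] 0.965
```

The classifier recovers 96.5% of the 200 planted genes at this seed
(49+50+49+45 = 193 category calls among 1,200 genes; the remainder are
unclassified nulls and the handful of planted genes whose estimated
fold changes fell on the wrong side of a threshold).

Pausing calls on the bundled NELF-C degron quantifications (GEO
GSE144786; seven representative YAP-target genes):

```r
call_pausing(nelfc_degron_quantifications())[, c("gene_id", "call")]
#>   gene_id                call
#> 1 FAM129C coordinated_loss_up
#> 2 SLITRK6 coordinated_loss_up
#> 3   APOBR coordinated_loss_up
#> 4 C8orf74 coordinated_loss_up
#> 5   FOLR3 coordinated_loss_up
#> 6   KCNC3 coordinated_loss_up
#> 7    HEG1 coordinated_loss_up
```

All seven promoters are retained at baseline, lose NELF-C occupancy on
degradation, and increase their gene-body output — the coordinated-loss
signature of pause release.

Contingency analysis of the bundled 75-patient cohort tables:

```r
res <- chi2_contingency(cohort_contingency_tables()$yap_by_grade)
sprintf("chi2 = %.2f, df = %d, p = %.4f", res$statistic, res$df, res$p)
#> [1] "chi2 = 4.00, df = 1, p = 0.0456"
```

A full synthetic run of every stage, with per-stage outputs and a JSON
manifest:

```r
m <- run_pipeline(default_config(outdir = "run1", seed = 7))
```

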