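# decoupleage

Tools for quantifying the decoupling of mRNA and protein expression over a
primate lifespan, and for linking that decoupling to posttranscriptional
regulators — RNA binding proteins (RBPs) mapped by CLIP experiments and
miRNAs with conserved predicted targets.

## The problem and the model

Bulk RNA-seq and label-free proteomics measured on brain samples spanning a
lifespan give, for every gene, two age trajectories: one for its transcript
and one for its protein. The package analyses their coupling separately in
a **developmental** and an **aging** interval, split at the age of sexual
maturity, on the fourth-root age scale `s = (age_days + 280)^0.25`:

1. **Quantification with reliability filters** — RPKM for mRNA
   (kept at RPKM ≥ 1 in more than 2/3 of samples), NSAF for protein
   (spectral counts / protein length, normalised per sample; genes need ≥ 2
   unique peptides, mean rescaled NSAF ≥ 1 and positive values in at least
   half the samples), TPM for miRNA.
2. **Age trajectories** — polynomial model selection in `s` (degrees 0–3,
   adjusted-r² criterion, F-test, Benjamini–Hochberg across genes), then a
   cubic smoothing spline per gene evaluated at 10 uniform points per
   interval.
3. **Concordance classification** — per gene and interval, the
   *exact-permutation* Spearman correlation between the mRNA and protein
   profiles (at n = 10 the smallest significant |rho| is 0.6485). A
   gene is *concordant* when coupling is significantly positive in both
   intervals, *discordant* when positive in development but negative in
   aging. A re-pairing permutation scheme (mRNA of one gene vs protein of
   random other genes) estimates the false discovery rate of the labelling.
4. **Patterns and regulators** — consensus k-means (modal partition over
   many restarts) sorts genes into the four lifespan patterns P1–P4;
   per pattern, discordant vs concordant genes are compared for RBP
   binding-site enrichment on exon unions (binomial targeted-fraction test
   plus one-sided rank-sum tests on site counts and densities, Bonferroni
   adjusted — the "key regulator" rules) and for seed-level hypergeometric
   enrichment of conserved miRNA targets, with a correlation-shift
   estimator of miRNA-mediated translational repression.

A fully seeded synthetic-data generator (`simulate_trajectories()`,
`simulate_regulators()`) emulates the study design — 14/12/12 samples over
98 years, four trajectory patterns, planted concordant/discordant coupling,
planted RBP-site and miRNA-target enrichment — so the entire pipeline is
testable end to end without any external data.

## Worked example

```r
library(decoupleage)

cfg <- simulation_config(n_genes = 1000, seed = 1)
run <- synthetic_decoupling_run(cfg, n_perm = 200)

glance(run$calls)
#> # A tibble: 1 x 6
#>   n_genes n_concordant n_discordant fdr_estimate alpha confident
#>     <int>        <int>        <int>        <dbl> <dbl> <lgl>
#> 1     102            0            0        0.920  0.05 FALSE

run$coupling
#> # A tibble: 1 x 4
#>   median_rho_dev median_rho_age            p     n
#>            <dbl>          <dbl>        <dbl> <int>
#> 1          0.964          0.630 0.0000000374   102

recovery_summary(run$calls, run$sim$truth, use = "raw")
#> # A tibble: 1 x 5
#>   n_called sensitivity_discordant specificity_discordant sensitivity_concordant
#>      <int>                  <dbl>                  <dbl>                  <dbl>
#> 1      102                  0.886                      1                  0.782
```

Reading these numbers: 102 of the 1,000 simulated genes survive the
protein-detection and age-dependence filters (the filters are deliberately
as harsh as the real ones). Coupling is much higher in development (median
rho 0.96) than in aging (0.63; paired Wilcoxon p ≈ 4e-8) — the planted
decoupling. The classification rule recovers 89% of the planted discordant
genes and mislabels none of the concordant ones. The `fdr_estimate` of 0.92
says that on this heavily patterned synthetic panel, re-paired
gene-to-gene profile combinations are themselves often significantly
correlated, so the global FDR gate withholds the `class` labels
(`confident = FALSE`) and accuracy is read from the classification rule
itself (`use = "raw"`); the methods vignette discusses why both behaviours
are correct.

`autoplot()` methods cover the main result types (`concordance_calls`,
`pattern_assignment`, `overlap_test`, `correlation_shift`), and
`tidy()`/`glance()` methods return tibbles for downstream work. The
file-based pipeline (`run_stage()`, `run_pipeline()`, and the thin CLI
wrapper in `inst/cli/decouple-age.R`) runs the same stages against TSV /
BED / GTF inputs with per-stage manifests.

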