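# salmospec

Testis transcriptome "specific activity" and maturation analysis for Atlantic
salmon (*Salmo salar*).

## The problem

At the onset of puberty, salmon testes grow much faster than the body: the
gonadosomatic index, GSI = gonad weight / body weight × 100, jumps from below
0.08% to 0.23% and beyond, serum androgens rise 7.5–17.5-fold, and the
germinative compartment (Sertoli cells plus germ-cell cysts) expands at the
expense of the interstitial compartment (Leydig cells, vessels, immune and
connective tissue). Bulk-testis expression profiling conflates two things: a
transcript can become more abundant per unit of testis RNA either because its
transcription is upregulated or simply because the compartment expressing it
now occupies a larger share of the tissue. `salmospec` therefore reports
differential expression between pubertal and immature testes as **higher /
lower specific activity (HSA / LSA)** rather than up-/downregulation, and it
ships a generative two-compartment simulator that makes the composition
confound explicit and testable.

The pipeline covers:

- **Biometrics and grouping** — GSI, Fulton's condition factor
  CF = W/L³ × 100, maturity grouping (immature: GSI < 0.08%; pubertal:
  GSI ≥ 0.23%; indeterminate in between), histology-table filters.
- **Per-gene specific activity** — log₂ expression ratio (log₂-ER, the
  difference of group means of log₂ intensities), per-gene Welch t-test, and
  the classification HSA iff log₂-ER > 0.8 and p < 0.05, LSA iff
  log₂-ER < −0.8 and p < 0.05 (both inequalities strict).
- **Gonad-specific genes (GSG)** — from a multi-tissue compendium, a gene is
  gonad-specific when its testis and/or ovary expression is ≥ 8-fold the
  average of all tissues and it is not expressed in any other tissue.
- **Functional-group shifts** — per annotated gene group, a one-sample test of
  whether the mean log₂-ER deviates from zero, with signed mean folds
  (fold = 2^m for m ≥ 0, −2^(−m) for m < 0).
- **Hormone statistics** — per-analyte Pearson correlation with GSI, group
  folds, and group t-tests.
- **Synthetic data with planted truth** — a seeded generator in which
  intensity(g, s) = [π_s·G_g·r + (1 − π_s)·S_g]·ε: π_s is the sample's
  germinative proportion (rising with maturity), G and S the compartment
  baselines, r a transcriptional regulation multiplier, ε log-normal noise.
  Every pipeline stage can be checked against the planted ground truth.

## Worked example

```r
library(salmospec)

study  <- simulate_study(seed = 1)   # cohort, expression, compendium, hormones
bundle <- run_pipeline(study, seed = 1)
bundle
#> <report_bundle>
#>   cohort: 20 fish (14 immature / 6 pubertal / 0 indeterminate)
#>   specific activity: 2000 genes, 501 HSA / 400 LSA / 1099 NS
#>   gonad-specific genes: 50 of 2000
#>   functional groups tested: 2 (1 significant)
#>   hormone analytes: 10
```

The 20-fish cohort has the study's bimodal GSI. Of 2000 simulated genes only
100 carry planted transcriptional regulation, yet 901 are classified HSA or
LSA: the rest of the signal is the composition confound — germinative-exclusive
genes drift up by about log₂(0.8/0.3) ≈ 1.41 and interstitial-exclusive genes
down by about log₂(0.2/0.7) ≈ −1.81 with no regulation at all.

```r
androgens <- names(sim_config()$hormone_folds)
gsi <- setNames(study$cohort$gsi, study$cohort$fish_id)
cors <- correlate_with_index(study$panel, gsi, summary_analytes = androgens)
attr(cors, "summary")
#> # A tibble: 1 × 3
#>   n_analytes mean_r   sd_r
#>        <int>  <dbl>  <dbl>
#> 1          5  0.917 0.0298
```

A single simulated panel gives a mean androgen–GSI correlation of 0.92 for
this seed; averaged over many replicate panels the mean sample r settles at
the calibrated population value of 0.83 (see the acceptance script below).

```r
round(compute_cf(1017, 41.3), 2)
#> [1] 1.44
```

Plot helpers: `autoplot()` on the per-gene result draws a volcano plot with
the classification cutoffs, `autoplot()` on the gene-set result a signed-fold
bar chart, and `plot_centered_heatmap()` the per-gene sample-centered log₂
profiles. `tidy()` and `glance()` return per-gene/per-set tibbles and one-row
summaries.

A thin command-line wrapper over the same functions is installed at
`inst/cli/salmospec.R` (subcommands `simulate`, `biometrics`, `classify`,
`screen`, `gsg`, `sets`, `run`).

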