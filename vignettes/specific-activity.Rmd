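---
title: "Specific activity in a growing testis: model, thresholds, and the composition confound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specific activity in a growing testis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmospec)
library(dplyr)
```

## Why "specific activity" instead of regulation

During male salmon puberty the testis grows disproportionately: the
germinative compartment (Sertoli cells and germ-cell cysts) expands while the
interstitial compartment (Leydig cells, vasculature, immune and connective
elements) shrinks as a fraction of the tissue. Bulk RNA measures transcript
abundance per unit of whole-testis RNA. A gene expressed only in the
germinative compartment will look "upregulated" in a maturing testis even if
no cell changed its transcription, purely because its compartment now makes up
more of the tissue. Since composition change and transcriptional regulation
cannot be separated in bulk data, the per-gene contrast is reported as
**higher or lower specific activity** (HSA/LSA), a deliberately neutral term.

## The analysis model

Fish are grouped by gonadosomatic index, GSI = gonad weight / body weight
× 100 (percent): **immature** below 0.08%, **pubertal** at or above 0.23%,
**indeterminate** in the gap. Indeterminate fish are excluded from group
statistics but kept in reports; the gap is real — endocrine activation can
precede histological change, so a fish can sit between the groups in ways GSI
alone does not resolve. Both thresholds are configurable
(`run_config()`), and the pubertal boundary is inclusive while the immature
one is strict, so the three intervals exactly partition `[0, Inf)`.

Per gene, on linear intensities floored at `intensity_floor` (default 1, so
log2 is always defined; background handling on this platform is otherwise
unspecified, and the floor is documented as a stand-in):

- **log2-ER** — mean log2 intensity in pubertal samples minus mean in immature
  samples. This is the log ratio of geometric group means, the standard choice
  for log-scale array data; a ratio of arithmetic means is available for
  sensitivity analysis via the linear scale if needed.
- **p-value** — two-sample t-test on the log2 intensities. Welch by default
  because the design is unbalanced (14 vs 6) and there is no reason to assume
  equal variances; `var_equal = TRUE` switches to the pooled test. When both
  groups are constant, p is defined as 1 for equal means and 0 otherwise, so
  degenerate genes never produce NaN or spurious calls.
- **class** — HSA iff log2-ER > 0.8 and p < 0.05; LSA iff log2-ER < −0.8 and
  p < 0.05; otherwise NS. Both inequalities are strict: a gene exactly at
  0.8 (1.75-fold) or p = 0.05 is NS. No multiple-testing correction is applied
  by default, mirroring the raw criteria; `p_adjust = "BH"` is available and
  clearly changes the operating point.
- **fold** — signed fold `2^m` for m ≥ 0 and `−2^(−m)` for m < 0, the printed
  convention in which magnitudes are symmetric and sign encodes direction.

Classification is antisymmetric by construction: swapping the group labels
negates every log2-ER and maps HSA to LSA exactly (a property test enforces
this).

**Gonad-specific genes.** From a genes × tissues compendium of linear-scale
means, the specificity score is the maximum of the gonad tissues (testis
and/or ovary) divided by the arithmetic mean over all tissues. Whether the
average includes the gonads themselves is not fixed by the verbal rule; they
are included by default (`include_targets_in_average`), which bounds the score
by the number of tissues, and a switch excludes them. A gene is called
gonad-specific when the score is at least 8 (inclusive — "eight-fold higher"
is read as a threshold attained) **and** no non-gonad tissue expresses it.
"Not expressed" needs an operational definition the rule does not give: a
tissue counts as expressed at or above
`max(absence_floor, absence_ratio × median(compendium))`, one scalar per
compendium (defaults 10 and 2). A single global threshold is robust to
platform scale and keeps the caller monotone: raising a non-gonad tissue can
only remove a call, never create one (a per-gene data-driven threshold can
violate that, because raising one tissue shifts the gene's own background).

**Functional groups.** For each annotated group with at least `min_set_size`
(default 10; the smallest group of interest in practice is about twice that)
genes present, the group's mean log2-ER is tested against zero with a
one-sample t-test, and the signed fold of the mean (one decimal) is reported
together with the counts of gonad-specific genes among the group's LSA and HSA
members. The one-sample t-test treats genes as independent; on real arrays
inter-gene correlation inflates its type-I error, so a gene-label permutation
test (`method = "permutation"`, 10,000 draws, seeded) is provided. Whether a
published "mean fold" is the fold of the mean log2 ratio or the mean of
per-gene folds is ambiguous; the former is the primary definition here (it is
the geometric-mean fold), and the latter can be computed from the per-gene
table if wanted.

**Hormones.** Per analyte: Pearson correlation with GSI (undefined — not an
error — for constant inputs or fewer than 3 pairs), pubertal-over-immature
fold of arithmetic group means on the linear scale (matching plain "x-fold"
reporting; geometric available), and a Welch t-test between the groups.

**Trigger-candidate screen.** Genes elevated in every sample of an "include"
set and in none of an "exclude" set, relative to the mean log2 intensity of a
baseline set. "Elevated" reuses the study-wide log2-ER cutoff of 0.8 since the
screen itself defines no threshold; it is configurable.

## What the simulator emulates

`simulate_study()` draws every input of the pipeline from a single seed (the
seed fans out to the stage generators by fixed offsets: cohort seed, matrix
seed + 1, compendium seed + 2, hormones seed + 3, annotation seed + 4).

**Cohort.** 14 immature fish with GSI uniform on 0.01–0.08% and 6 pubertal
fish uniform on 0.23–0.60%; body weight normal (1017 ± 82 g), condition factor
normal (1.44 ± 0.08) with fork length derived; histology labels assigned by
maturity (pubertal fish get SPC/SPT/SZ as most advanced cell type with a
dominating type no more advanced); oocyte observations planted only among
immature fish at rate 3/14, reflecting that intersex observations occur at low
GSI.

**Expression.** The two-compartment mixture
`I(g, s) = [π_s G_g r + (1 − π_s) S_g] · ε` with:

- `π_s`, the germinative proportion, truncated-normal per fish (immature mean
  0.3, pubertal mean 0.8, SD 0.05). The study's histology gives only ordinal
  compartment sizes, so 0.3/0.8 are illustrative round values spanning a
  strong composition shift; they are defaults, not measurements. π is drawn
  per fish rather than set deterministically so confound tests face realistic
  sampling variation.
- `G_g`, `S_g` log-normal baselines (log2 mean 7, SD 1.5 — mid-range intensity
  with ~3 decades of spread, typical of one-color arrays). 20% of genes are
  germinative-exclusive (S = 0), 20% interstitial-exclusive (G = 0), 60%
  shared. Shared genes take a common base level with a mild compartment bias
  (log2 SD 0.25): compartments expressing a gene at wildly independent levels
  would make most "shared" genes effectively exclusive, which contradicts
  the closed-form behavior the mixture is meant to exhibit (a balanced shared
  gene is exactly flat under pure composition change).
- `r = 2^2` for the 5% of genes planted as transcriptionally regulated, acting
  on the germinative term in pubertal samples only. Because regulation enters
  through the germinative term, it is planted among shared genes, where it is
  observable; regulating an interstitial-exclusive gene would be invisible by
  construction.
- `ε` multiplicative log-normal noise with log2-scale SD 0.25, the
  moderate replicate noise of a well-run array experiment; intensities are
  analyzed on the log2 scale, so multiplicative noise is the natural choice.

With zero noise and jitter the mixture reproduces its closed forms to machine
precision: germinative-exclusive genes shift by exactly log2(0.8/0.3) ≈ 1.415,
interstitial-exclusive ones by log2(0.2/0.7) ≈ −1.807, and balanced shared
genes not at all. That is the composition confound in pure form, and the test
suite asserts the pipeline classifies those genes HSA/LSA with **zero**
transcriptional regulation planted.

**Compendium.** Ten tissues (testis, ovary, liver, muscle, brain, gill, skin,
kidney, spleen, heart). Planted gonad-specific genes sit at a fixed low
background of 8 intensity units outside the gonads and at `margin × x0` in
testis or ovary (alternating), where `x0` is the intensity putting the
specificity score exactly at 8; margin 1 therefore plants genes exactly on the
boundary (the inclusive rule calls them), and the default margin 2 plants them
comfortably above it. Decoys violate the rule both ways: ubiquitously high
genes and "leaky" genes as high in liver as in the gonad. When generated as
part of a study, the compendium covers the same gene universe as the
expression matrix so specificity calls join onto the differential results.

**Hormones.** Five androgen-like analytes are linear in GSI, anchored to the
realized group means so the planted pubertal/immature folds (7.5, 10, 12.5,
15, 17.5, spanning the observed range) are exact in the absence of noise, plus
signal-proportional (constant-CV) Gaussian noise censored at zero as at a
detection limit. The CV is solved per analyte from the variance decomposition
r² = var(signal)/var(total) using the population moments of the GSI mixture,
so the population correlation with GSI equals the configured 0.83 — the
calibration is analytic, nothing is fitted to a sample. Proportional noise is
the realistic choice for steroid panels (roughly constant CV across the
measuring range), keeps concentrations non-negative, and preserves group
means, so planted folds are also recovered under noise. Two consequences are
worth knowing: the mean *sample* Pearson r at n = 20 sits slightly above the
population value (heteroscedastic noise leaves the low-signal immature fish
nearly on the line, a small-sample effect of order +0.02, still within the
±0.03 recovery band the tests assert), and analytes with planted folds above
roughly 11.6 have a noise-free signal that crosses zero at the lowest immature
GSI, where censoring takes over — a structural consequence of demanding strict
linearity, group-mean folds, and non-negativity at once. Five cortisol-like
analytes are generated independent of GSI.

### What the simulator does *not* emulate

Real probe structure (a 44K oligo array collapses to ~20–40K gene-level
values; the default here is 2000 genes for fast tests), array normalization
artifacts, intensity-dependent variance, inter-gene correlation beyond the
shared per-fish π, partial compartment overlap of "exclusive" genes,
continuous histological progression (stages are assigned by group, not by a
latent developmental clock), and any relation between a gene's compendium
values and its testis-matrix baselines. Passing the recovery tests therefore
shows the pipeline is correct *under the stated generative model*; it does not
certify performance on a particular real dataset, and counts obtained from a
real accession will differ from any simulated ones.

## Numerical choices and degenerate inputs

- All logs are base 2. Intensities ≤ 0 or missing are floored (default 1.0)
  before logging; values between 0 and the floor are kept.
- Cutoff comparisons: classification strict (> 0.8, < 0.05), gonad-specificity
  inclusive (≥ 8), maturity boundaries immature-strict / pubertal-inclusive.
- Zero variance: per-gene and per-analyte two-sample tests return p = 1 for
  identical constant groups, p = 0 for distinct constant groups; one-sample
  set tests on identical values return `NA` ("undefined"), reported, never
  dropped silently.
- Percentages and folds print to one decimal; the underlying columns keep full
  precision except the gene-set `mean_fold`, which is the rounded display
  value alongside the exact `mean_log2_er`.
- Ties in `rank_sets()` break by group label, so output order is stable.
- `alpha` must lie strictly inside (0, 1); an effectively zero alpha (e.g.
  1e-12) classifies nothing on null data.
- The truncated-normal draws use the inverse-CDF construction, so they are
  exactly reproducible from the seed with no rejection loops.

## Open decisions taken

- Whether the fish excluded as a hormone outlier also left the correlation
  estimate is not documented in the source material; both modes are possible
  via the `summary_analytes`/subsetting arguments, neither is asserted.
- Whether the all-tissue average includes the gonads: included by default,
  switchable.
- t-test variant: Welch primary, pooled behind a flag.
- Mean fold of a gene set: fold of the mean log2-ER (primary).
- The upstream normalization applied by the original analysis system before
  its log2 ratios is unknown; floor-plus-log2 is this package's documented
  convention, so absolute agreement with accession-specific gene counts is out
  of scope by design.

## Problem sizes in the test suite

Unit and property tests run on 2–200 gene fixtures; calibration tests use
2000 genes × 20 samples (per-gene null), 1000 groups × 20 genes (set-level
null), 200–500 replicate hormone panels of 20 fish, and a 2000-gene compendium
— sizes chosen so the full suite completes in a few minutes while Monte-Carlo
bands stay tight (binomial SE below 0.005 at those counts).
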