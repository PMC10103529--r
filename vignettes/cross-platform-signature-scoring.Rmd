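---
title: "Cross-platform rank-based signature scoring: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform rank-based signature scoring: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigbridge)
```

# The problem

Targeted expression panels (NanoString-style, a few hundred probes) and
whole-transcriptome sequencing (WTS, ~20k genes) are both used to profile the
immune state of tumour biopsies. Single-sample signature scores summarise a
gene set from one sample's internal gene ranking, so they are unaffected by
which other samples happen to be in the cohort — but they are *not*
automatically comparable across platforms, because a panel's genes occupy a
biased (mid/high) region of the whole-transcriptome rank scale. sigbridge
implements the rank engine, three ranking calibrations that address this, the
diagnostics that justify them, and a response-prediction workflow that
quantifies how well a model trained on panel scores transfers to WTS scores.

# The score

For a sample with `n` ranked genes, every gene gets an integer competition
rank starting at 0 (ties share the lowest rank of their block), mapped to a
relative rank in [0, 1]. For an undirected gene set of size `m`, with `c` the
median of the sample's relative ranks, the raw statistic is the mean over set
members of `|rank − c|`. It is normalised by the smallest and largest mean
deviation achievable by `m` distinct positions on the ideal tie-free grid
`0 … n−1`, then clipped to [0, 1]: a set packed at the centre of the ranking
scores 0, a set split across the extremes scores 1. Because only within-sample
ranks enter, any strictly monotone per-sample transform of the counts — in
particular every per-sample scaling step of the normalisation chain — leaves
scores exactly unchanged on tie-free data. The test suite asserts this
equality exactly; on real data background flooring introduces ties among
low-signal probes, which is why empirical raw-vs-normalised agreement is near
1 rather than exactly 1.

Normalisation bounds are computed on the ideal tie-free grid even when ties
exist, keeping them data-independent; achievable bounds computed from the
sample's own rank multiset are available via `bounds = "achievable"`. For the
calibrated rank scales (stable-gene, skewed) the same uniform-grid bounds are
used: they keep scores on a common [0, 1] scale across calibrations, which is
the point of the cross-platform comparison.

# The three ranking calibrations

**No stable gene** ranks the matrix as is. On WTS data this is the `all`
variant; ranking only the platform-overlap genes is the `part` variant.

**Stable genes** stratifies a sample's ranks by `k` designated stable genes
(here: the panel's housekeeping probes). A gene in level `L` (the number of
stable genes strictly below it) at within-level fractional position `f` gets
relative rank `(L + f)/(k + 1)`; the stable genes themselves pin the level
boundaries at `i/(k + 1)`. The spec of the within-level position,
`f = (competition rank among the level's non-stable genes + 0.5)/level size`,
makes the map strictly monotone in the counts.

**Skewed ranks** fits, by OLS, the sorted per-gene median WTS relative ranks
of the overlap genes against uniform quantiles `(i − 0.5)/m` and applies the
fitted affine map `r → clip(a + b·r, 0, 1)` to the panel's uniform ranks —
placing them in the rank region the same genes occupy within a whole
transcriptome. Both regression orientations are implemented
(`orientation = "ranks_on_x"` inverts the fit); the default regresses the
observed ranks on the quantiles. An option excludes the lowest-rank fraction
of genes from the fit, since the low tail departs from linearity in skewed
panels; the default fits all genes. A noteworthy consequence of the affine
form: per-sample Spearman agreement between skewed-panel scores and any fixed
WTS score table is identical to that of the uncalibrated scores (a strictly
increasing per-sample map cannot change rank correlations); the skew changes
score *levels* — slopes and intercepts — not orderings.

# Rank-consistency diagnostics

Whether a gene set can calibrate ranks across platforms is an empirical
question. For a gene pair with untied reference order (per-gene median WTS
relative rank), the pairwise consistency is the fraction of panel samples
preserving that order; a gene's score is the average over all partners, and
within-sample ties count as non-preserving. Genes with average consistency
above 0.7 (and optionally among the smallest rank-MAD genes; MAD is unscaled)
are stable-gene candidates. Random, order-free panel ranks centre these
scores at 0.5, which the tests verify by Monte Carlo.

# Differential testing and the clinical table

Signature scores are compared between responders (RECIST CR/PR, or SD longer
than 6 months without progression) and non-responders (PD, or SD of at most
6 months) with a two-sided Mann–Whitney test — exact for combined n ≤ 25
without ties, tie-corrected normal approximation otherwise — and
Benjamini–Hochberg adjustment across all scored signatures. One sample per
patient enters (repeats dropped, then first sample ID per patient). Rows with
adjusted p ≤ 2×10⁻⁴ and |Δ median| ≥ 0.1 form the top tier. Cohort-level
treatment×response and biopsy-site×response tables are tested with Pearson's
chi-squared (Yates-corrected only in the 2×2 case), warning on expected
counts below 5.

# Response model

Feature selection repeats an L1-penalized logistic path (glmnet) over a grid
of 100 log-spaced penalties spanning four orders of magnitude below the
smallest all-zero penalty. Each repeat draws a stratified ten-fold split from
a deterministic sub-seed, picks the penalty maximizing mean out-of-fold AUC,
and records the non-zero features; the path solver uses a convergence
threshold of 1e-5, which on these problem sizes halves runtime with identical
selections. Features chosen in at least half the repeats (inclusive at the
cutoff) enter an unpenalized logistic fit, with a top-2-by-frequency fallback
when nothing passes. Separation triggers a flagged ridge-stabilized fallback.
One caveat the tests document: because repeats perturb only the fold split,
not the data, the luckiest chance-correlated feature in a null dataset *is*
stably selected; stability here guards against penalty-path noise, not
against dataset-level overfitting. Evaluation uses the rank-statistic AUC
(ties count one half), confusion metrics at the default 0.5 threshold and at
the training-ROC Youden optimum (ties to the lowest threshold), MCC with the
zero convention when a marginal is empty, and sensitivity reported as missing
when no sample is classified responder. A patient-ID guard refuses evaluation
when training and target cohorts share patients.

# The synthetic cohort

Real paired panel/WTS immunotherapy cohorts are access-restricted, so the
package ships a generator whose defaults are the study conditions of the test
suite; every parameter is a named `cohort_config()` field.

* **Latent expression.** Per-gene log-normal baseline (`meanlog 2`,
  `sdlog 1.5`); per-patient biological noise `bio_sd = 1` log-unit (so a
  signature `effect` of 0.5 is half a latent SD); negative-binomial counts
  with `dispersion = 0.05` and per-sample library factors on both platforms.
* **Panel membership.** Endogenous probes are drawn with logistic weighting
  on the baseline rank at rate `panel_rank_bias = 4`, reproducing the
  concentration of panel genes in the mid/high WTS rank region (median WTS
  relative rank of panel genes ≈ 0.65 at the default).
* **Signatures as modules.** All signature sets draw their genes from the
  upper half of the panel baseline distribution — signature collections are
  sets of *expressed* genes, and an undirected score only responds to
  activity that moves a set coherently away from the median rank. Each
  signature's members share a per-patient activity (`module_sd = 0.25`);
  without co-regulation the signature-size/reproducibility relationship has
  no mechanism. `module_sd` is calibrated so that the generator meets its
  prescribed recovery property (a 0.5-SD, 15-gene responder shift detected
  at FDR ≤ 0.05 with ≥ 90% power at n = 120).
* **Housekeeping probes.** High baseline and low biological variance
  (`bio_sd_hkg = 0.1`) on both platforms, but on the panel their baselines
  are re-drawn at dispersed quantiles (25th–99.5th of the endogenous
  distribution) in shuffled order — panel housekeeping ranks are dispersed
  while WTS housekeeping ranks concentrate near the top, which is what makes
  the housekeeping calibration the weakest cross-platform option.
* **Tissue composition.** WTS observations add block-structured per-sample
  drift (`composition_sd = 1`, three disjoint gene programs over non-panel
  genes): bulk biopsies vary in tumour/stroma/immune content, and this
  variation moves large coherent blocks of the transcriptome that a targeted
  panel never sees. This is the mechanism behind the overlap-restricted
  (`part`) scoring out-transferring all-gene scoring in cross-platform
  prediction; with a perfectly stable whole-transcriptome reference frame the
  opposite holds.
* **Batches and repeats.** Cartridge-level scale offsets (`batch_count = 3`,
  `batch_sd = 0.15`) apply to the panel only; technical repeats re-observe a
  patient's panel counts with multiplicative log-normal noise and,
  optionally, another cartridge's offset.
* **Design labels.** Treatment and biopsy site are assigned independently of
  response, matching the published cohort's null associations. An
  `overlap_fraction` marks the subset of samples observed on both platforms,
  enabling the train-on-panel-only / test-on-overlap design.

What the generator does **not** emulate: FFPE degradation, probe-level
hybridization chemistry, copy-number or mutational effects, realistic
melanoma co-expression structure beyond the module model, and platform-
specific GC/length biases. Passing tests therefore demonstrate correctness
of the pipeline's statistics and the qualitative cross-platform mechanics,
not clinical performance on real cohorts.

# Problem sizes and numerical choices

The test suite runs at a 2000-gene transcriptome with a 150-gene panel and
cohorts of 40–120 patients; these sizes preserve every qualitative property
of the full-scale data (the generator scales to 20k/770 unchanged).
Monte-Carlo checks use 50 replicates (power, prediction ordering), 100
repeats (selection stability), and 1000 draws (consistency null). Geometric
means error on zeros rather than adding pseudocounts, since background
flooring precludes zeros in the normalisation chain; the panel-standard
calibration floors standard counts at the background before ratioing, and
uses the first cartridge as reference. Ranking ties follow competition
("min") ranking throughout the scoring engine, while Spearman correlations
use conventional average ranks — a correlation convention, not a score
convention.
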