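---
title: "Concomitant-metabolite normalization and exhaustive LDA panel search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concomitant-metabolite normalization and exhaustive LDA panel search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Targeted plasma metabolomics platforms such as the Biocrates MxP Quant 500
report many small molecules as relative abundances (chromatographic
area-under-curve values), not molar concentrations. Relative abundances are
comparable across individuals only after accounting for demographic
covariates and for the large inter-individual scale differences that all
members of a biochemical family share. This package implements a pipeline
for case-control diagnostic modeling of such data — here framed around
Alzheimer's disease (AD) versus cognitively normal controls (NC) — in four
stages: cleaning, concomitant-metabolite normalization, residual-based
group contrasts, and an exhaustive panel search with a linear discriminant
classifier.

# The normalization model

The central device is the *concomitant metabolite*: within each
biochemical family one member, $m_c$, is used as a covariate that carries
the family-wide scale. For each other member $m$ the package fits, on
complete cases, the ordinary least squares model

$$\log_{10}(m) = \beta_0 + \beta_a\,\mathrm{Age} + \beta_s\,\mathrm{Sex}
  + \beta_{as}\,\mathrm{Age}\!\times\!\mathrm{Sex}
  + \beta_f\,\mathrm{Fasting} + [\,\delta\,\mathrm{Group}\,]
  + \beta_c \log_{10}(m_c) + \varepsilon,$$

with Sex coded 0/1 (male/female) and Group 0/1 (NC/AD). Two variants are
first-class outputs:

* **with-Group**: used for concomitant scoring, for the per-metabolite
  group contrast (direction = sign of $\hat\delta$, p-value = its
  two-sided t-test), and for the residuals behind the family correlation
  heatmaps;
* **without-Group**: used for the residuals that feed classification, so
  that class information cannot leak into the features through the
  residualization step.

The residual $e_m = \log_{10}(m)_{\mathrm{obs}} -
\log_{10}(m)_{\mathrm{pred}}$ is the portion of variability the covariates
and the concomitant do not explain; it is the feature every downstream
stage consumes.

## Concomitant scoring and selection

`score_concomitants()` tries every member of a family as $m_c$, fits the
with-Group model to each other member, and averages the adjusted $R^2$ and
the overall regression F-test p-value across those fits. Candidates are
ranked by mean adjusted $R^2$, ties by smaller mean F p-value, then by
name. Two points here were genuinely open and are package decisions:

* The reported $R^2$ average is the *adjusted* $R^2$ (the model-size
  penalized form), which is the quantity a selection table naturally
  reports alongside the overall F-test.
* Statistical rank is not the whole story in practice — domain knowledge
  about which member is biologically stable matters and cannot be
  computed. That enters through the explicit `overrides` argument of
  `select_concomitants()`; the conventional six-family choice (SDMA,
  TDCA, spermine, 3-indoleacetic acid, succinate, DHA) ships as
  `study_concomitants()`.

# Cleaning rules

Three filters run in a fixed order:

1. **Named exclusion** removes listed low-quality samples from the whole
   cohort.
2. **Below-LOD filtering**: per family, a sample missing more than
   `max_missing_frac` (default 0.2) of the family's metabolites is removed
   from that family. Remaining missing values are never imputed; every
   model fit uses its own complete cases. The 0.2 default quantifies
   "multiple missing values"; no published figure exists, and the flag is
   exposed.
3. **Outlier exclusion**: per family, values beyond `sd_mult` (default 3)
   standard deviations of their metabolite are flagged, and a sample with
   strictly more than `max_outlier_frac` (default 10%) of the family
   flagged is removed from that family. Flags are computed on the log10
   scale by default — the scale of all downstream modeling — with
   `scale = "raw"` available; a zero-SD metabolite flags nothing.

The per-family character of filters 2–3 matters: a sample can be excluded
from one family and retained in the others, which is why family-wise
sample tallies differ. Exclusion masks the sample's entries in that family
rather than dropping the row, and a fully masked sample counts as absent
from the family, making each filter idempotent.

# Classification

`fit_lda()` is two-class Gaussian LDA with a shared covariance: unbiased
pooled within-class covariance $S$, discriminant direction $a = S^{-1}
(\mu_{AD} - \mu_{NC})$, rescaled so $w^\top S\, w = 1$ (the unit
within-group-variance convention under which published LD1 coefficients
are stated; the global sign is arbitrary). Posterior scores are
$P(\mathrm{AD}\mid x)$, a logistic function of the projection, using
*empirical* class priors — an open choice, adopted because it reproduces
the observed behavior that the optimal posterior threshold sits near the
positive-class fraction in imbalanced cohorts. Classification is strict:
AD iff score > threshold, with 0.58 the package-wide default fixed
threshold; `scan_thresholds()` optimizes accuracy over a grid with ties
broken by better sensitivity/specificity balance, then the lower cutoff.

LOOCV refits only the discriminant per fold; the residuals stay as fitted
on the full cohort. This matches a pipeline that residualizes first and
cross-validates classification afterwards. The induced optimism is real
but small (the residualization model has no access to labels in the
without-Group variant); a strict protocol can re-residualize per fold by
rebuilding the residual matrix on each training subset before calling
`fit_lda()` — the functions compose to allow it, at ~n times the cost.

# Exhaustive panel search

`search_panels()` enumerates every k-subset of the candidate pool
(concomitants excluded — they are normalizers, not features), evaluates
each with the LDA at the fixed threshold, and keeps a bounded top-n, so
memory does not depend on $C(n,k)$. Per-subset fits reuse class means and
centered Gram matrices computed once over the pool; the LOOCV variant
downdates the pooled Gram matrix per fold by a rank-one
(Sherman–Morrison) update rather than re-inverting, and the two routes are
verified equal in the tests. Samples are restricted to complete cases
over the candidate pool, the merged-sample convention under which every
panel is evaluated on the same cohort. Subsets with singular pooled
covariance are skipped and counted. Ranking is accuracy, then
sensitivity, then specificity, then lexicographic feature names — an
invented but fixed tie-break, since published tables are sorted without a
stated rule.

A note from the package's own validation: ranking by *resubstitution*
accuracy at a fixed threshold recovers a planted panel unreliably, because
among many decoys some 3-of-4 panel plus a lucky noise feature can match
or beat the true panel in-sample, and saturated accuracies produce ties
that the lexicographic rule resolves arbitrarily. LOOCV-ranked search is
the robust reading — cross-validation is precisely what filters those
overfitted swaps — and is what the acceptance script measures
(superset-of-panel recovery at k = 5).

# The synthetic cohort generator

`generate_cohort()` is the generative mirror of the normalization model:
per family, a log-normal concomitant ($\log_{10} m_c \sim N(3, 0.3)$ by
default — only relative values matter on this platform, so the location is
a plausible AUC scale) drives every member through the affine model above,
plus per-member disease shifts $\delta$ of both signs and Gaussian log10
noise. Below-LOD censoring masks a Binomial number of the *lowest* values
per metabolite; gross outliers are additive $\pm k\cdot$SD shifts with
$k \in [4, 6]$, so a 3-SD rule detects them by construction. Counts of
both are recorded in a generation log. All draws descend from one seed
through per-family substreams, so adding a family never perturbs another —
a property the tests assert.

Defaults describe the study conditions the pipeline targets: 94 AD and 64
NC samples, ages 55–90, balanced sexes, fasting 2–14 h, six families
sized 30/14/14/4/8/12 with the conventional concomitant names, group
shifts cycling up/down/null at 0.12 log10 units, noise SD 0.15, censor
rate 0.02, outlier rate 0.005. Those effect sizes make four-metabolite
panels classify in the high-0.8 range on clean synthetic data — stronger
than the 0.75–0.80 a real cohort yields, because the generator's world is
exactly the model's world. What passing tests show is therefore that the
*machinery* is correct (recovery, calibration, algebra), not that real
plasma data will reach any particular accuracy: the generator has no
medication or diet confounding, no platform batch structure, no
heavy-tailed biological outliers, and its missingness is driven by
abundance alone.

# Numerical choices and degenerate inputs

* OLS is fitted by `stats::lm`; rank-deficient designs error with the
  aliased terms named, rather than silently dropping columns. Fits
  require at least 8 complete cases (and always at least two more than
  the number of terms).
* Singular pooled covariances error in `fit_lda()` (naming the feature
  set) and are skipped-and-counted inside the search.
* BH adjustment delegates to `stats::p.adjust` after validating the
  inputs; the correction scope is per family by default (significance is
  framed within each family's heatmap) and switchable to global. The
  choice of method and scope is a package decision; no published method
  statement exists for it.
* An exactly zero Group coefficient is reported as "down in AD" by the
  strict sign rule; correlation matrices use pairwise-complete
  observations with the pair count recorded per cell.
* Seeds are 32-bit; per-family substream seeds are reduced modulo
  2^31 - 21 and all derived seeds stay below 2^31.

# Problem sizes used in the tests and acceptance script

The tests run the search on candidate pools of at most 25 metabolites
(seconds per run) and verify the combinatorics of the full 76-candidate,
k = 5 space — 18,474,840 panels — in closed form plus a streaming tally on
a reduced instance. Recovery and calibration simulations use 100 seeds
for concomitant recovery and group-shift power (n = 150, shift 0.3,
noise 0.05), 15–20 seeds for the null calibrations, and 10 seeds for
planted-panel recovery; cohort sizes mirror the 139–158-sample scale of
the motivating data. A full k = 5 enumeration over 76 candidates runs the
same code path and is a matter of hours on one core, with `top_n`
bounding memory.

# Known limitations

* The concomitant is chosen per family once, on the full cohort;
  selection is not cross-validated (matching the pipeline order), so the
  scores feeding the choice are mildly optimistic.
* LOOCV does not re-residualize per fold by default (see above).
* Pairwise-complete correlation matrices can be slightly non-PSD under
  heavy missingness; no shrinkage is applied.
* The exhaustive search is exact but combinatorial; it is not a variable
  selection method and deliberately offers no greedy shortcut.
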