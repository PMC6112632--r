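---
title: "Validating polytomous symptom scales: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating polytomous symptom scales: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvssrasch)
```

This vignette is the package's account of its methods: the models it
fits, the numerical and design choices behind them, what the synthetic
data generator does and does not emulate, and the limits of what the
test suite demonstrates.

## The measurement model

The package treats a questionnaire as a fixed form of polytomous items
with ordered categories. The core model is the partial credit model
(PCM), the polytomous Rasch model in which every item has its own step
structure. A person with measure $\theta_n$ (logits) responding to item
$i$ with $m_i$ steps at thresholds $\delta_{i1},\dots,\delta_{im_i}$
(logits) lands in category $x \in \{0,\dots,m_i\}$ with probability

$$P(X_{ni}=x)=\frac{\exp\sum_{k\le x}(\theta_n-\delta_{ik})}
{\sum_{h=0}^{m_i}\exp\sum_{k\le h}(\theta_n-\delta_{ik})},$$

the empty sum being zero. The PCM (rather than a common rating-scale
structure) is the right default for symptom scales whose items use
different category wordings and counts: for the bundled CVSS17
specification, fifteen items carry 3 categories and two carry 4, so a
shared threshold structure is not even well-formed. Raw scores are
sufficient for $\theta$, which is what makes a score-to-measure table
and score-range severity cutoffs meaningful.

Assumptions worth keeping in view: a single latent dimension per fitted
scale, local independence given that dimension, and monotone category
structures. The residual-PCA summary (`residual_pca()`) is the built-in
check of the first assumption; fitting subscales separately
(`subscale_spec()`) is the remedy when it fails.

## Estimation choices

**Joint maximum likelihood.** `fit_pcm()` alternates Newton–Raphson
updates of person measures and item step thresholds, the estimation
scheme of classical Rasch software. JMLE is chosen deliberately over
conditional or marginal ML: the published numbers this workflow is
meant to mirror come from JMLE software, and JMLE needs no assumption
on the person distribution. Its known drawback — mild bias in item
parameters for short tests — is accepted and left uncorrected
(`STBIAS`-style correction is intentionally not applied); with 6–17
items the bias is small against the standard errors involved, and
applying it would complicate comparison with the common default.

**Identification.** The mean item difficulty (mean of each item's
thresholds, averaged over items) is constrained to zero after every
sweep; the compensating shift is applied to the person measures, which
leaves the likelihood unchanged.

**Convergence** is declared when the largest parameter change in a
sweep falls below 0.005 logits *and* the largest person raw-score
residual falls below 0.01, within 200 sweeps; non-convergence is an
error by default. These are the conventional operating tolerances of
this estimation style; the toy-matrix oracle test tightens them to
$10^{-7}$ to compare against a grid search at 0.001-logit resolution.

**Extreme scores.** Persons at the scale minimum or maximum carry no
likelihood information and would diverge; they are excluded from
estimation and afterwards assigned finite measures by moving their raw
score 0.3 score units inward before inverting the test characteristic
curve (TCC). The same adjustment produces the first and last rows of
the score-to-measure table, so the full published score range gets
finite measures. 0.3 is the customary fractional-score adjustment; it
is a visible argument (`extreme_adjust`) rather than a constant.

**Degenerate inputs.** Categories never observed in the data are
collapsed out (with a warning) so codes are contiguous; items without
observed variance are an error; Newton steps are clamped to 1 logit and
parameters to ±10 logits to keep early sweeps stable.

`score_to_measure()` inverts the TCC by Newton iteration; the TCC is
strictly increasing, so the root is unique and the table is strictly
monotone — a property the suite asserts, alongside a bisection oracle.

## Fit, separation, targeting, dimensionality

Residual-based statistics follow the standard definitions: with score
residual $y = x - E[X]$ and model variance $W$, outfit is the
unweighted mean of $y^2/W$ and infit the information-weighted
$\sum y^2 / \sum W$, per person and per item; both have expectation
near 1 under the model. Person statistics are undefined for extreme
scorers, and items are judged over non-extreme persons.

The person separation index is
$\mathrm{PSI} = \mathrm{SD}_{\mathrm{true}} / \mathrm{RMSE}$, where
RMSE pools the model standard errors of the non-extreme person measures
and $\mathrm{SD}_{\mathrm{true}}^2 = \max(0,\ \mathrm{Var}(\theta) -
\mathrm{RMSE}^2)$; reliability is $\mathrm{PSI}^2/(1+\mathrm{PSI}^2)$,
an identity the suite checks exactly.

Targeting is mean item difficulty minus mean person measure — zero
when the instrument is centred on its sample, negative when persons sit
above the items.

Dimensionality uses a PCA of standardised residuals
$z = y/\sqrt{W}$: the largest eigenvalue of the item-by-item residual
correlation matrix ("first contrast", in item units) plus the raw
variance explained by the measures, computed as
$\mathrm{Var}(E)/(\mathrm{Var}(E) + \overline{y^2})$ over observed
cells. This is an empirical-variance formulation; software that
computes the decomposition from model variances can differ by a few
percentage points, which matters for interpretation (a B-grade
boundary) but not for the contrast eigenvalue used to flag
multidimensionality.

## Levels of performance

`count_levels()` implements the sample-independent strata count: with a
score-to-measure table spanning measure range $R$ whose non-extreme
rows have SE root-mean-square $\mathrm{RMSE}$,

$$L = \frac{R}{3\,\mathrm{RMSE}}, \qquad
\mathrm{reliability} = \frac{L^2}{1+L^2}.$$

The 3-error-unit spacing is the conventional criterion for centres
"statistically different at $p<.05$". The formula reproduces all three
published (levels, reliability) pairs for this instrument family —
5.8→0.97, 4.7→0.96, 3.3→0.92 — which is the validation available for
it; both the multiplier and whether extreme-score SEs enter the pooling
(`include_extremes`, default off, since the extrapolated extreme SEs
are artefacts of the 0.3 adjustment) are arguments, so an alternative
convention is a mode, not a code change.

Cutoffs divide the measure range into $\lceil L \rceil$ equal-width
bands; each band edge maps back to the smallest raw score whose measure
reaches it, giving half-open score intervals $[b_j, b_{j+1})$ with the
top interval closed — a boundary score belongs to the upper level.
Levels holding less than 1% of the scored sample merge into their lower
neighbour (the bottom level merges upward), repeating until stable;
1% is the occupancy below which a severity grade has no clinical
resolution, and it reproduces the published 6→5 collapse behaviour.

## Factor structure and discriminant confirmation

The classical factor workflow intentionally mirrors the SPSS default
chain so its numbers are comparable with published tables: Pearson
correlations on listwise-complete persons (not polychoric — offered
nowhere in this package's defaults because the published workflow used
product-moment correlations; complete-case analysis also matches the
"subjects who answered every item" design), KMO and Bartlett
suitability checks, principal components retained at eigenvalue > 1,
varimax rotation with Kaiser normalisation, and regression-method
factor scores standardised per factor. Communality preservation under
rotation and the trace identity are asserted in the suite.

Items are assigned to the factor with loading over 0.5; an item whose
top two absolute loadings both clear the threshold *or* lie within 0.1
of each other is flagged as cross-loading (the margin catches the
"0.48 vs 0.54" pattern that a hard threshold would silently assign),
and a published-grouping override table resolves flagged items.

Discriminant analysis asks whether the two factor scores alone can
reproduce the severity levels. Classification uses Fisher linear
discriminant functions with equal priors (the SPSS "all groups equal"
default; proportional priors are a flag) and reports *resubstitution*
accuracy, because that is what the conventional "% of cases correctly
classified" figure denotes; leave-one-out accuracy is computed
alongside as the honest generalisation estimate. Group comparisons
across the gender×presbyopia groups use the tie-corrected
Kruskal-Wallis test with Dunn's post hoc z tests, Bonferroni-adjusted
and capped at 1.

## DIF screening

Two methods, both reported on the item-difficulty metric (positive =
harder for the first group) so their signs agree:

- **Mantel-Haenszel**: persons are matched on raw scale score; strata
  are pooled (adjacent scores merged) until both groups have ≥5 persons
  per stratum, the standard sparse-stratum practice. Size is minus the
  common cumulative log-odds pooled over strata and category splits
  (Liu-Agresti style); significance is the Mantel chi-square (1 df).
- **Anchored logit-difference**: the target item's thresholds get a
  uniform per-group shift re-estimated with person measures and all
  other items anchored at the overall fit, one pass, no purification
  iterations; size is the shift difference, with a Wald p from the
  combined anchored SEs.

Items with |size| > 0.5 logits are flagged — the conventional screening
threshold for this instrument class. Recovery of an injected 0.6-logit
shift and sign antisymmetry under group relabelling are tested.

## Quality grading

`grade_quality()` maps a subscale's report onto A/B/C grades. The cited
grading guidelines do not print their numeric boundaries, so the
package's defaults are the boundary set consistent with every published
grade for this instrument family: misfitting-item count 0→A, ≤2→B;
variance explained ≥60→A, ≥40→B; first contrast <1.5→A, ≤2.0→B;
PSI ≥2.5→A, ≥2.0→B (so a PSI of 1.63 grades C while 2.61 grades A);
level reliability ≥0.9→A, ≥0.8→B; |targeting| ≤1→A, ≤2→B; DIF flags
0→A, ≤2→B. Every boundary is configuration, not code.

## The synthetic-data generator

`simulate_responses()` produces data with the structure the analysis
assumes, so the whole pipeline is testable without any participant
data. Defaults are the emulated study conditions:

- 796 persons in four gender×presbyopia groups drawn with probabilities
  proportional to 135/64/219/182, presbyopes aged 40–65;
- two latent traits (external/internal symptoms) correlated at
  $\rho = 0.6$, each item driven by the trait of its subscale
  (simple structure; a `cross_loading` option mixes both traits for one
  item to mimic a cross-loading item);
- group mean shift of +0.4 logits for presbyope women over a baseline
  of +0.3, so the sample sits above the items and targeting comes out
  near −0.4;
- latent SD 1.3 logits, calibrated so the synthetic total scores
  reproduce the published sample's dispersion (SD ≈ 7.65) and sampling
  adequacy (KMO ≈ 0.94) — at SD 1.0 the factor structure is visibly
  weaker than the emulated data's and a spurious third Kaiser component
  appears in a noticeable share of replicates;
- item step thresholds spread over roughly [−1.8, 1.8] logits, with
  difficulty offsets dealt round-robin to the subscales so both span
  the same range; the default CVSS17 specification gives 4 categories
  to one item per subscale (A4, A22) — the published scoring charts are
  PDF appendices, so which two items carry the fourth category is a
  package default, not a reproduced fact;
- 1.7% completely-at-random cell missingness, leaving roughly three
  quarters of persons with complete forms, matching the emulated
  complete-case fraction (600/796).

What the generator does **not** emulate: informative missingness,
response styles, local dependence between items, differential category
usage across groups, and the exact (non-additive) published subscale
scoring charts — subscale scores in the default specification are plain
category sums. Consequently, passing tests demonstrate that the
*methods* recover known structure under the model's own assumptions;
they do not certify the instrument itself, and pipeline quantities
computed on synthetic data (variance explained, discriminant accuracy,
Kruskal-Wallis H) sit systematically below the values a real,
sharply-structured sample produces.

## Problem sizes and runtime choices

The test suite runs its recovery checks at the emulated study sizes
(600 persons for factor-partition and measure recovery, 796 for the
end-to-end pipeline) and scales Monte-Carlo style checks to modest
replicate counts (10–50) so the whole suite completes in well under a
minute of CPU; the acceptance script repeats the partition-recovery
experiment at 50 replicates. Every stochastic check fixes its seed.

## Known limitations

- JMLE item parameters carry the usual small-sample bias; comparisons
  against marginal-ML software will differ by a few hundredths of a
  logit on short subscales.
- The raw-variance-explained formula is the empirical variant; values
  are comparable across runs of this package but only approximately
  with other software.
- The Wright-strata arithmetic is validated through published
  (levels, reliability) pairs rather than an independent reference
  implementation; the multiplier and SE pooling are therefore exposed
  as options rather than frozen.
- `read_responses()` reads CSV; spreadsheet submissions must be
  exported first.
- The discriminant step assumes a shared within-group covariance; with
  severity levels induced from the same scores being classified,
  resubstitution accuracy is optimistic by construction — use the
  reported leave-one-out figure for generalisation claims.
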