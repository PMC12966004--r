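---
title: "Evaluating long-term heat tolerance from paired CK/HS seedling trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating long-term heat tolerance from paired CK/HS seedling trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotol)
```

## The evaluation model

Heat-tolerance screens measure a panel of physiological and morphological
indices on the same genotypes under a control (CK) and a heat-stress (HS)
regime. The quantity of interest is not any raw trait value but how much of
it a genotype *retains* (or how strongly it is induced) under stress, so the
pipeline's first transformation is the heat-resistance coefficient

$$h_{gj} = \frac{\bar{x}^{HS}_{gj}}{\bar{x}^{CK}_{gj}},$$

the ratio of condition means for genotype $g$ and index $j$. Replicates are
averaged *before* the ratio: a ratio of means is far more stable than a mean
of per-replicate ratios when control replicates are noisy, and per-replicate
CK/HS pairing is not meaningful in a growth-chamber design where different
seedlings sit in each chamber. The ratio is kept on the unit scale
(1 = unchanged); rendering it as a percentage is a display choice that the
scoring below cannot see.

The genotype × index ratio matrix is column-standardized (mean 0, unit
variance, $n-1$ denominator) and eigendecomposed — correlation-matrix PCA.
The correlation matrix is the only defensible choice here: the panel mixes
enzyme-activity ratios, pigment ratios and length ratios whose variances are
not comparable, and classical factor-analysis software defaults to the same
standardization. Each retained component gives every genotype a
comprehensive index $CI_{gi}$ (score on the unit-norm eigenvector). Scores
are then min–max normalized across genotypes into membership values

$$U_{gi} = \frac{X_{gi} - X^{min}_i}{X^{max}_i - X^{min}_i} \in [0, 1],$$

weighted by the component's share of retained variance
$W_i = P_i / \sum_{i'} P_{i'}$, and combined into the composite tolerance
value $H_g = \sum_i U_{gi} W_i$. By construction $\sum_i W_i = 1$, every
$U$ column spans exactly $[0,1]$, $H \in [0,1]$, and a genotype that tops
every retained component scores exactly 1. Because centering, correlation
PCA and min–max normalization each absorb affine maps, rescaling any single
index column by $a x + b$ ($a > 0$) — a unit change, a percent-vs-ratio
convention — leaves every $H$ unchanged to machine precision. The test suite
asserts this end to end.

Seedling damage is scored independently of the index panel: each seedling is
graded 0 (no symptoms) to 4 (more than half the cotyledon/true-leaf area
dehydrated or yellowing), and a genotype's counts $N_0..N_4$ give the heat
injury index $HII = \sum_i i N_i / (4N) \times 100$. The printed form of
this formula is parenthesis-ambiguous; it is read with $4N$ in the
denominator, the only reading under which an all-class-4 population scores
100 rather than 4000, matching the universal convention for injury indices.
HII is deliberately *excluded* from the PCA input: it serves as the
validation target (a sound $H$ must correlate negatively with it), and a
validation target folded into the score would make the check circular.

## Tunable parameters

* `variance_threshold` (default **0.80**): retain the smallest component set
  reaching this cumulative variance share. With a ~10-genotype, ~9-index
  screen this typically retains 3 components (roughly 84% of variance);
  `n_components_override` fixes the count for exact replication of a
  published run.
* `anchor_index` (default **"Chl a"**): eigenvector signs are arbitrary, but
  the membership function is not sign-invariant, so orientation must be
  pinned. Each retained component is flipped so its loading on the anchor —
  chlorophyll-a retention, the lead tolerance indicator, biologically
  expected to rise with tolerance — is non-negative; if that loading is zero
  (within 1e-10) or the anchor is absent, the largest-magnitude loading is
  made positive instead. Deterministic and platform-independent. If a
  published analysis used the opposite orientation for some component, the
  anchor must be overridden to reproduce its exact $H$ values.
* `alpha_enter` / `alpha_remove` (defaults **0.05 / 0.10**): stepwise
  entry/removal significance levels, the classical defaults of the
  statistical packages this procedure originates from. `alpha_enter <
  alpha_remove` is enforced to prevent enter/remove cycling.
* `n_groups` (default **3**): tolerance groups cut from the dendrogram,
  labelled I (highest mean $H$) downward.
* `index_list`: which indices enter the PCA. User-configurable because
  screens differ on whether morphological indices (hypocotyl length) belong
  in the panel alongside physiological ones; the default is every index in
  the data.

## Stepwise selection and prediction

With $H$ as response and the $h$ columns as candidates, forward entry picks
the candidate with the smallest partial-F p-value (lexicographic label on
ties, so column order never matters) if it clears `alpha_enter`; backward
removal then drops any included predictor at or above `alpha_remove`;
iterate to a fixed point. Three guards: steps that would leave ≤ 1 residual
degree of freedom are refused (with 10 genotypes at most 7 predictors can
ever enter); candidates with tolerance below 1e-8 against the current model
are skipped and logged; and once the fit is numerically exact
($R^2 \ge 1 - 10^{-12}$) no further entries are considered, because partial
F statistics computed on floating-point residuals are meaningless. The final
model reports the raw-scale equation (coefficients on $h$-ratio units plus
intercept) *and* beta-standardized coefficients; published equations of this
kind are sometimes labelled "standardized" while carrying an intercept, and
only the raw-scale reading is dimensionally consistent with $H$ values near
0.5 for healthy genotypes. `predict_h()` applies the equation to new
genotypes' ratios unclipped, flagging predictions outside $[0,1]$ — a
genotype more sensitive than anything in the calibration panel legitimately
extrapolates below 0.

One behaviour of stepwise selection is worth stating because it surprises:
under a global null, the rate at which *some* noise candidate ends up in the
model is roughly $1-(1-\alpha)^p$ per step, not $\alpha$ — the min-p race
across $p$ candidates inflates selection. What equals `alpha_enter` exactly
is the per-candidate calibration: a single candidate judged on its own
partial-F p-value enters 5% of the time under the null. The acceptance
checks test the calibrated property and, for signal recovery, that the true
predictors are *contained* in the selection — with six decoys at
$\alpha = 0.05$ an extra decoy tags along in roughly a quarter of
replicates, for any correct implementation.

## Grouping

$H$ is one-dimensional, so clustering is agglomerative with squared
Euclidean distance and average linkage — again the classical defaults — cut
at `n_groups`. On 1-D data this yields contiguous groups (each group an
interval of sorted $H$), and on well-separated data it coincides with the
exhaustive optimal within-group sum-of-squares partition; both properties
are asserted against brute-force oracles in the tests. Validation against
HII is advisory: a non-negative correlation triggers a prominent warning,
not a failure, since the right response is to inspect index orientation,
not to abort a screen.

## The synthetic trial generator

`generate_trial()` emulates the screen's design: 10 genotypes, each with a
latent tolerance factor $\theta \sim U(0,1)$; six indices measured in 3
replicates under both conditions; 30 seedlings graded per genotype. Four
benefit indices respond as $h(\theta) = 0.3 + 0.7\theta$ (a fully sensitive
genotype keeps 30% of the trait under stress, a fully tolerant one is
unaffected — the span typical of pigment retention and enzyme induction
data); two hazard indices (stress-forced hypocotyl elongation, a
membrane-damage marker) respond as $h(\theta) = 1.6 - 0.9\theta$, chosen to
keep $h$ positive on $[0,1]$ with comparable dynamic range. Replicates are
Normal with a 5% coefficient of variation, truncated at zero — unbiased in
practice at this CV, and documented as biased if pushed to large CVs, where
a log-normal model would be preferable. Injury grades are
Binomial$(4, \mathrm{clamp}(1-\theta+\varepsilon))$ per seedling with one
noise draw $\varepsilon \sim N(0, 0.05)$ per genotype, so the expected
injury index is exactly $(1-\theta) \cdot 100$ when noise is off. Each index
and the injury scorer consume independent child streams hashed from (seed,
label): adding an index never perturbs existing columns, and a fixed seed
reproduces a trial byte for byte.

The generator is single-factor and linear in $\theta$ — the weakest
structure under which a composite PCA score is a consistent estimator of
the latent ranking. That is a feature for testing (the noiseless pipeline
must recover Spearman$(\theta, H) = 1$ exactly, and does) and a limitation
for realism: real screens have multi-factor structure, genotype × index
interactions, heteroscedastic replicates and missing cells, none of which
the defaults emulate. Passing the recovery checks therefore shows the
machinery is correct, not that any real panel is as clean.

## Numerical choices and degenerate inputs

Constant index columns (zero variance) and constant component scores abort
with named errors rather than producing NaN memberships; missing CK/HS
pairs are hard errors (min–max normalization is undefined on partially
observed genotypes, so complete-case is the only coherent policy); CK means
≤ 0 are domain errors for the ratio. Exact ties at a component's min or max
share the 0 or 1 membership without jittering. Scores use unit-norm
eigenvectors; eigenvalue-scaled scores give identical $H$ because the
membership step absorbs per-component scale — asserted by a test, so the
choice is recorded but inconsequential. Orthonormality and
eigenvalue-conservation are checked to 1e-8/1e-10 against closed forms
(2-index case: $1 \pm r$) and an independent power-iteration oracle.

## Problem sizes

The test suite and acceptance script run trials at the design's native
scale (10 genotypes × 6 indices × 3 replicates), 100 seeds for the
stochastic medians, 1000 replicates for null calibrations, and 1000
randomized cases for the scoring identities; the full suite completes in
under two minutes on a single core.
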