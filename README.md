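# thermotol

Composite heat-tolerance evaluation for seedling phenotyping trials.

## The problem

Screening crop germplasm for long-term heat tolerance means growing the same
genotypes under a control regime (CK, e.g. 26°C/22°C day/night) and a heat
stress regime (HS, e.g. 42°C/28°C) and measuring a panel of physiological and
morphological indices — chlorophyll contents, antioxidant enzyme activities
(SOD, POD, CAT), hypocotyl length, germination rate — plus a visual damage
score per seedling. No single index separates tolerant from sensitive
genotypes reliably; indices overlap and disagree. `thermotol` implements the
standard membership-function evaluation system that fuses the whole panel
into one tolerance value per genotype, for breeders and physiologists doing
germplasm screens.

## The method

For each genotype *g* and index *j*, replicate measurements are averaged per
condition and converted to the **heat-resistance coefficient**

&nbsp;&nbsp;&nbsp;&nbsp;*h*<sub>gj</sub> = mean under HS / mean under CK,

a dimensionless ratio (1 = unchanged by stress). The genotype × index matrix
of ratios is column-standardized and decomposed by correlation-matrix PCA.
The retained components (smallest set reaching 80% cumulative variance by
default) give each genotype a comprehensive index CI per component, which is
min–max normalized across genotypes into a **membership function value**

&nbsp;&nbsp;&nbsp;&nbsp;*U*<sub>i</sub> = (*X*<sub>i</sub> − *X*<sub>min</sub>) / (*X*<sub>max</sub> − *X*<sub>min</sub>),

weighted by each component's share of retained variance, *W*<sub>i</sub> =
*P*<sub>i</sub> / Σ*P*<sub>i</sub>, and summed into the **heat tolerance
value**

&nbsp;&nbsp;&nbsp;&nbsp;*H* = Σ *U*<sub>i</sub> · *W*<sub>i</sub> ∈ [0, 1].

Seedling damage is summarized independently as the **heat injury index**
from five-grade counts *N*<sub>0</sub>..*N*<sub>4</sub>:

&nbsp;&nbsp;&nbsp;&nbsp;HII = Σ(*i* · *N*<sub>i</sub>) / (4*N*) × 100 ∈ [0, 100],

and a sound H should correlate negatively with HII. Stepwise OLS regression
(partial-F entry/removal at 0.05/0.10) then distils H into a minimal
predictive equation over a few measurable indices, applicable to new
genotypes; hierarchical clustering of H (average linkage, squared Euclidean)
assigns tolerance groups I, II, III with Group I the most tolerant.

A seeded synthetic trial generator with a latent tolerance factor θ per
genotype makes the whole pipeline testable end to end: benefit indices
respond as *h* = 0.3 + 0.7·θ, hazard indices (stress-forced hypocotyl
elongation, membrane damage) as *h* = 1.6 − 0.9·θ, and injury grades follow
Binomial(4, 1 − θ), so Spearman(θ, H) measures how well the composite score
recovers the planted ranking.

## Worked example

```r
library(thermotol)

trial  <- generate_trial(simulation_config(seed = 7))
report <- run_pipeline(trial$pheno, trial$injury)
print(report)
```

```
Correlation-matrix PCA: 1 of 6 components retained (98.770% of variance)
Eigenvalues: 5.9262, 0.0379, 0.0225, 0.0092, 0.0030, 0.0013
H = 0.795*SOD + 0.677*Chl a -0.518
R^2 = 0.999, F = 6492.545, p = 3.63e-12, n = 10
H vs HII: Pearson r = -0.973 (p = 2.25e-06, n = 10)

Per-genotype summary (top of table):
# A tibble: 10 × 5
   genotype      H H_rank group   hii
   <chr>     <dbl>  <int> <fct> <dbl>
 1 G01      1           1 I       2.5
 2 G02      0.331       5 II     65.8
 3 G03      0.0656      9 III    89.2
 ...
```

One latent factor drives all six simulated indices, so a single component
captures ~99% of the variance and H is a clean monotone readout of it:
`recovery_statistic(trial$truth, report$genotypes)` returns Spearman = 1.
The per-genotype table gives each genotype's composite value H (1 = most
tolerant in this panel), its rank, its tolerance group, and its observed
injury index; the strong negative H-vs-HII correlation is the internal
validation that the composite score tracks real damage. The fitted equation
says that in this trial SOD induction and chlorophyll-a retention suffice to
predict H; `predict_h()` applies such an equation to new genotypes'
coefficient ratios. `write_run_report(report, "out/")` writes the
per-genotype table, loadings, eigenvalues and a self-contained JSON report.

Real data enter as two tidy CSVs: phenotype measurements
(`genotype,index,condition,replicate,value` with condition `CK`/`HS`) and
injury counts (`genotype,class0,...,class4`); `run_pipeline()` accepts the
file paths directly.

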