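---
title: "Dynamic multi-family QTL mapping: models, calibration and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic multi-family QTL mapping: models, calibration and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynqtl)
```

`dynqtl` maps quantitative trait loci (QTL) whose effects change over
developmental time, in populations made of several partially connected
biparental families of doubled haploid (DH) lines. This vignette is the
package's account of its science: the generative model behind the simulator,
the statistical models behind each estimator, the calibration of the default
preset, and the numerical conventions a user should know before trusting a
number.

## 1. The population simulator

### Crossing design and meiosis

A `crossing_design()` lists biparental families; parents may recur across
families ("partially connected"), which ties allele effects together across
families and motivates the family-effect-plus-common-marker-effect scan
model below. The default preset uses six fully homozygous parents and four
families of 131/120/200/196 DH lines (647 total): families 1–2 share one
parent and families 3–4 share another, so the design graph has two parents
of degree two and four of degree one.

Each DH line is produced by one simulated meiosis of the family's F1,
followed by genome doubling: the line is homozygous at every marker and
carries only parental alleles. Crossovers between adjacent markers at
distance $d$ cM occur with the Haldane probability
$r = \tfrac12(1 - e^{-2d/100})$, independently across intervals and lines
(no crossover interference); markers on different linkage groups assort
freely. Haldane's map function is the simplest model consistent with cM
input; with real maps estimated under interference the simulated
recombination fractions are mildly conservative, which is irrelevant for the
estimators tested here.

Markers are biallelic and scored 0/1. In a DH population a dominant
presence/absence assay is effectively codominant (no heterozygotes exist),
so the 0/1 coding carries the full information. A configurable fraction of
calls (default 2%) is masked at random after phenotype generation, so
missingness is an observation process, never causal.

Marker polymorphism: every simulated marker is guaranteed to segregate in at
least one family (monomorphic columns are redrawn). The preset's *QTL*
markers are additionally forced to segregate in **all four** families. This
models major development loci segregating throughout adapted elite material
and is required for the preset to be a useful test bed: a QTL segregating in
a single family of ~130 lines is near the detection boundary of the scan,
and a reference simulation whose ground truth is undetectable by design
cannot validate anything.

### The phenotype model

For line $i$, environment $j$ and stage $t$ the plot-level observation is

$$y_{ijt} = m_t + f_{(i)t} + \sum_q x_{iq} b_q(t)
          + \sum_{(q,q')} x_{iq} x_{iq'} b_{qq'}(t)
          + u_i(t) + g_{ij}(t) + e_{ijt},$$

with stage mean $m_t$ (defaults 49/69/81, BBCH-like), small family
deviations $f$, additive QTL effects $b_q(t)$, epistatic interactions coded
as the product of 0/1 columns, a polygenic term $u$, a GxE deviation $g$ and
a plot error $e$. QTL are classified *persistent* (nonzero at every stage),
*stage-specific* (zero at one or more stages) or *sign-switching* (opposite
signs at some pair of stages); the constructor validates the classes.

The three random terms are multivariate normal **across stages**, each with
its own correlation matrix. The cross-stage correlation of noise terms is
deliberate and physical: the same plots are scored repeatedly as the crop
develops, so plot errors and GxE deviations at consecutive stages are far
from independent. It is also a mathematical necessity: with stage-specific
QTL in the architecture, the high observed phenotypic correlations between
stages cannot be reproduced by genetic covariance alone.

Scores are kept continuous by default (`round_scores = FALSE`): all the
regression machinery assumes a continuous response, and rounding to integer
BBCH codes is a presentation step, not a data-generating one.

The trial layout is partially replicated: one plot per line and environment
(default `n_env = 4`, standing for 2 locations x 2 years), plus a second
plot for a random 20% of lines per environment. The harmonic-mean
replication per line-environment cell is then $\bar r = 1/0.9 \approx 1.11$.
Checks and spatial field trends are not modelled (see Limitations).

### Calibration of the default preset

The preset is calibrated so that the *simulated* data reproduce the
phenotypic summary statistics of a real triticale developmental-stage study:
entry-mean heritabilities near 0.90/0.85/0.72 at the three stages, and BLUE
correlations near 0.84 (DS1–DS2), 0.74 (DS2–DS3), 0.69 (DS1–DS3).

The calibration is analytic with one empirical ingredient:

1. The QTL effect profile is fixed first (three persistent QTL with effects
   0.85–1.0 BBCH units, two DS1-specific QTL, one sign-switching QTL on
   group 6A with effects +0.9/−0.35/−0.9, and one epistatic pair on groups
   1B x 3B with interaction 1.7). The 3x3 covariance matrix of the QTL
   genetic values across stages, $\Sigma_{QTL}$, is measured by simulating
   genotypes (it depends on the design's allele-frequency structure, which
   has no convenient closed form under the polymorphism constraints).
2. The total genotypic variance is held at $\sigma^2_G = 3.3$ per stage;
   polygenic variances absorb the remainder,
   $\sigma^2_{poly}(t) = 3.3 - \Sigma_{QTL}(t,t)$.
3. GxE variances are set to (0.792, 1.32, 2.904) — the increasing share of
   GxE at later stages mirrors what repeated scoring of development shows —
   and plot-error variances solve the entry-mean heritability identity
   $h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GxE}/E +
   \sigma^2_\varepsilon/(E\bar r))$ for the targets.
4. Cross-stage covariances needed to hit the BLUE correlation targets are
   allocated proportionally between the polygenic term (correlation capped
   at 0.98) and the noise terms (capped at 0.90), and the resulting
   correlation matrices are checked for positive definiteness.

Verification by simulation (20 seeds): mean estimated $h^2$ =
0.900/0.849/0.718 against targets 0.90/0.85/0.72, mean BLUE correlations
0.838/0.688/0.738 against 0.84/0.69/0.74. The first of these pairs is also
what `scripts/acceptance.R` recomputes.

Two calibration choices deserve emphasis. The preset's QTL effects (~0.5
genotypic SD each) and the epistatic interaction (~0.9 genotypic SD) are at
the large end of what field studies report. They are chosen so that
detection power at the multiplicity-corrected thresholds is high (~0.9 for
the interaction at the 5.3e-5 threshold; near 1 for the main effects), which
the package's dynamic-layer tests require: a test bed whose ground truth is
detected in half the seeds validates nothing. Real architectures have many
more, mostly smaller QTL; the cross-validation machinery (Section 6) is
where that regime is exercised.

## 2. BLUEs and variance components

`compute_blues()` fits the two-way fixed-effects model
`y ~ line + environment` by least squares with sum-to-zero environment
contrasts, so each BLUE is the line's adjusted mean at the average
environment; with balanced data this is the plain line mean. The line
factor is absorbed analytically (the environment effects are estimated from
line-centred data), so the fit costs one small regression however many
lines there are. No spatial or check adjustment is attempted. Lines without
observations are listed in an attribute, and missing BLUEs propagate as
missing — scans drop such lines per trait.

`estimate_variance_components()` fits
`y = mu + env + line + line:env + error` by REML (`lme4`), with environment
fixed and line and line-by-environment random; negative variance solutions
are handled by the fitter's boundary (clamped at zero). Entry-mean
heritability uses the identity above with $E$ and $\bar r$ taken from the
realized design ($\bar r$ = harmonic mean of replicate counts over observed
line-environment cells). Significance of each random term is a
likelihood-ratio test against the model without it, with the p-value halved
because the null value lies on the boundary of the parameter space. With a
single environment the GxE component is inestimable and is returned as `NA`
with $h^2$ computed on the reduced formula.

## 3. The multi-family association scan

The scan model for marker $q$ is

$$Y = 1\mu + X_f M_f + X_q b_q + \sum_{c \ne q} X_c b_c + \varepsilon,$$

where $Y$ are the per-line BLUEs, $X_f$ the family incidence matrix (each
line in exactly one family), and $X_c$ stepwise-selected cofactors that
absorb background QTL variation. The marker is tested with a 1-df F test of
the full against the reduced (no $b_q$) model on the lines complete for $q$
and the active cofactors; the allele-substitution effect $\hat b_q$ is
reported on the 0/1 coding with reference allele 0.

**Cofactor selection** (`select_cofactors()`) is forward-backward stepwise
regression minimising $SBC = n\ln(RSS/n) + k\ln(n)$, $k$ counting all fitted
parameters including intercept and family effects, which are never removed.
The search is deterministic: ties are broken by the larger RSS reduction
(equivalently the smaller p-value at equal df) and then by map order. An
empty cofactor set is a legitimate outcome. Missing genotype calls are
family-mean imputed *within the selection only*, so all candidates compete
on identical observations; the scan itself always refits complete-case.
Under a pure-noise trait the SBC still admits a handful of cofactors (the
best of hundreds of candidate F statistics exceeds $\ln n$ with appreciable
probability); this is a property of the criterion, not a defect — the Holm
correction downstream, not the cofactor set, controls the error rate.

**Cofactor exclusion window.** Besides the tested marker itself and any
marker genotypically identical to it, cofactors within 10 cM (configurable)
of the tested marker on the same linkage group are dropped from that
marker's fit, standard composite-mapping practice that stops a neighbouring
cofactor from absorbing the tested QTL; `cofactor_window_cM = 0` reproduces
the literal $c \ne q$ rule.

**Multiplicity.** Holm's step-down procedure is applied to the markers
actually tested ($m$ recorded in the scan metadata; duplicate columns are
collapsed to one representative and inherit its statistics). Holm rejections
are always a superset of Bonferroni rejections at the same level, and the
family-wise error under a global null stays at its nominal level — both are
tested.

## 4. The epistasis scan

For every unordered marker pair the model gains the two main effects and
their product-coded interaction, and the interaction alone is tested with a
1-df F test. Cofactors are *not* included by default — the minimal model
matches the displayed extension terms, and a flag can add them. Pairs
missing any of the four two-locus genotype classes, or whose interaction
column is collinear with the main effects, are inestimable: skipped and
counted, never reported as zero.

The significance threshold divides $\alpha$ by the number of independent
region pairs, assuming two regions per linkage group:
$\alpha / \binom{2L}{2}$. The default map has $L = 22$ (21 nominal
chromosomes with one represented as two linkage groups), giving
$0.05/946 \approx 5.3\times10^{-5}$; with `n_groups = "auto"` semantics the
map's own group count is used. Reference-allele flips change the sign of
$\hat b_{qq'}$ but not the p-value. A thinning parameter (test one marker
per $w$ cM) bounds the $O(m^2)$ scan on dense maps; the default is no
thinning.

## 5. Explained genotypic variance

The proportion of genotypic variance explained by a detected marker set is
$p_G = 100\, R^2_{adj} / h^2$, where $R^2_{adj}$ is the adjusted
coefficient of determination of the marker terms **beyond the family-only
baseline**:

$$R^2_\Delta = \frac{RSS_{family} - RSS_{full}}{RSS_{family}}, \qquad
R^2_{adj} = 1 - (1 - R^2_\Delta)\frac{n - F}{n - F - k}.$$

Family differences are design structure, not explained genotypic variance;
keeping them out of both numerator and baseline makes $p_G$ comparable
across designs. $p_G > 100\%$ is reported with a warning rather than
truncated — the estimator's optimism is real information, and the
cross-validation module exists precisely to quantify it.

Per-QTL shares are *sequential* partial R² from a simultaneous fit: markers
enter in order of scan p-value (ties by map order), and marker $i$ receives
$(RSS_{i-1} - RSS_i)/RSS_{family}$, so collinear QTL credit the more
strongly associated marker. The unadjusted shares sum exactly to
$R^2_\Delta$; for reporting they are scaled proportionally by
$R^2_{adj}/R^2_\Delta$ and divided by $h^2$. `temporal_pg_profile()` applies
the same accounting per stage to the union of detected regions (each region
represented by its best member at that stage), which is how the temporal
trajectories of QTL contributions are produced.

## 6. Cross-validation and selection bias

`run_cv()` re-runs the *entire* detection pipeline (cofactor selection,
scan, Holm) on estimation sets (ES) of a family-stratified fivefold split
and validates on the held-out test sets (TS). Stratification keeps every
family present in every fold (within one line of exact proportionality),
necessary because family effects are in the model. The number of runs
defaults to 20 (100 ES scans).

$p_G$-ES is the in-sample accounting of Section 5 on the ES. $p_G$-TS is
the adjusted squared correlation between ES-model predictions and observed
TS BLUEs, divided by the same full-data $h^2$; negative values clamp to
zero, and folds whose ES scan finds nothing contribute zeros (counted, not
dropped). Predictions and observations are **centred within TS families**
before correlating: the ES quantity measures marker variance beyond the
family baseline, so the TS quantity must too — correlating un-centred
predictions would credit between-family variance to the TS side and can
even make the apparent bias negative. An unadjusted variant
(`ts_estimator = "squared_cor"`) is available. $h^2$ is estimated once on
the full data and reused in every fold; re-estimating per fold would
conflate phenotypic and genotypic cross-validation.

The headline statistic is the relative bias
$100\,(p_G\text{-ES} - p_G\text{-TS})/p_G\text{-ES}$, computed from the
aggregated means. In a 647-line simulation with 30 modest QTL plus an
untagged polygenic background at $h^2 = 0.85$, the package's acceptance
suite measures a relative bias of several tens of percent — in-sample
$p_G$ is substantially optimistic whenever detection is borderline, which
is exactly the regime of real data.

## 7. The dynamic layer

QTL from different stages are matched into regions by single-linkage
clustering within linkage groups: two significant markers share a region iff
they are on the same group within `window_cM` of each other, and chains
merge (the behaviour of overlapping intervals; an anchor-based alternative
was rejected as order-dependent). The default window of 5 cM reads a
"10-cM interval surrounding the QTL" as ±5 cM of total width 10; the
parameter is exposed because ±10 is an equally defensible reading. Each
region's representative is its member with the smallest p-value across
stages.

`venn_counts()` partitions regions by stage membership (all 7 classes of 3
stages reported, zeros included) and reconciles with per-stage totals;
`marker_venn_counts()` does the same at marker level, where linked markers
tagging one QTL count separately — the two partitions need not agree, and
both are reported.

`progression_scan()` maps the *change* between consecutive stages: the
progression trait $\Delta_i = BLUE_i(t+1) - BLUE_i(t)$ goes through the full
pipeline (own cofactors, own Holm correction). A QTL with equal effects at
both stages cancels from $\Delta$; one whose effect flips sign appears with
roughly twice its magnitude — so progression QTL and sign-change reports
corroborate each other. A constant $\Delta$ (to numerical tolerance) aborts
with an explicit error. `sign_change_report()` lists regions significant at
two or more stages whose effect signs disagree, with the stage pair and
magnitudes.

## 8. Numerical conventions

* All least-squares fits use pivoted QR (`.lm.fit`); aliased coefficients
  are `NA`, and rank changes decide estimability (e.g. a pair's interaction
  must raise the rank by exactly one to be testable).
* Nested F tests treat an RSS below $10^{-12} \times TSS$ as an exact fit:
  a reduced model that already reproduces the response gives $F = 0, p = 1$;
  a full model that alone fits exactly gives $F = \infty$ with p clamped to
  `1e-300` so multiplicity corrections (which contract p in (0, 1]) accept
  it.
* Markers monomorphic in the analysed lines are skipped and logged, never
  tested; markers with identical genotype columns are collapsed and the
  duplicates flagged with their representative.
* Ties in stepwise selection and in p-value ordering break by map order,
  making every search deterministic; all randomness flows from one master
  seed through named sub-streams (parents, meiosis, phenotypes, missing
  calls, CV splits), so equal seeds give byte-identical outputs.
* Holm's correction requires p-values in (0, 1]; `NA` p-values are never
  rejected and do not count toward $m$.

## 9. Problem sizes used by the test suite

The package's checks run at sizes chosen to exercise every code path while
staying desk-scale: calibration recovery and the dynamic layer use 20
simulated studies of the full preset (647 lines x 1000 markers); oracle
equivalence uses 110 random small instances (20–60 lines); the family-wise
error simulation uses 200 null scans of 500 markers x 300 lines; the
selection-bias study uses one 647-line population on a 500-marker map with
20 cross-validation runs. The acceptance script repeats the calibration
recovery (20 seeds) and completes in under a minute.

## 10. Limitations

The simulator is a test bed, not a field-trial emulator. It omits crossover
interference, segregation distortion, map errors, spatial field trends,
check-based adjustment and selection during DH production; phenotypes are
continuous rather than ordinal BBCH codes; GxE is exchangeable across
environments rather than structured by location and year. Consequently,
passing tests demonstrate that the estimators recover the architectures the
generator encodes under realistic noise, heritability and family structure —
they do not certify performance under spatial confounding, ordinal scoring
or strongly distorted segregation. The preset's QTL are larger than typical
real effects (by design, see Section 1); power statements made by the test
suite are statements about the preset, not about any particular crop study.
The scan model is single-marker biallelic regression across families:
kinship corrections, haplotype tests and founder-probability models are out
of scope.
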