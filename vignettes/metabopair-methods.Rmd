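---
title: "Methods: paired differential analysis of untargeted LC-MS metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired differential analysis of untargeted LC-MS metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`metabopair` analyzes untargeted LC-MS feature tables from paired
(crossover) designs, of the kind produced by peak-picking software after
alignment: rows are molecular features keyed by accurate mass (m/z, Da)
and retention time (min); columns are injections — study samples, pooled
QC injections interleaved through the run, and blanks. Intensities are
relative (detector response), non-negative, with zeros marking
below-detection values. The motivating design is a two-arm dialysate
crossover in hemodialysis patients (acetate vs citrate dialysate, AD/CD),
with each subject sampled pre- and post-session in each arm, but the
machinery is generic: any comparison of two injection groups paired by a
metadata key works.

The pipeline starts at the feature table. Raw-spectrum processing (peak
detection, retention-time alignment, gap filling, isotope grouping) is out
of scope, as is MS/MS spectral matching, which enters only as boolean
evidence flags for confidence leveling.

# Stage order and rationale

`run_pipeline()` executes: medFC normalization → QC-LOESS drift
correction → QA filter → paired volcano pre-selection → PCA and OPLS-DA
with validation on the volcano-selected features → VIP / jack-knife /
fold-change selection cascade → annotation.

Normalization precedes filtering, and medFC precedes the LOESS step. The
relative order of the two normalizations was an open choice; medFC first
removes gross per-injection dilution so that the per-feature LOESS curve
models instrument drift only, rather than a mixture of drift and dilution.

## medFC normalization

The reference profile is the feature-wise median over all study
injections. Each non-blank injection is divided by the median, over
features positive in both the injection and the reference, of
intensity/reference. Blanks pass through: they carry no sample material,
and an all-zero column has no defined fold change against the reference
(a non-blank injection sharing no positive feature with the reference is
an error instead). Under the log-normal generative model below, the
per-injection factor estimates the injection's multiplicative dilation
exactly in expectation; the package tests verify recovery of injected
dilution factors {0.5, 1, 2} to within 1% at low noise. Because the
reference is re-estimated after normalization, idempotence is statistical
rather than bit-exact: second-pass factors are 1 to within well under a
percent in the tested regimes.

## QC-anchored LOESS drift correction

Per feature, a local-linear LOESS curve (default span 0.75, configurable;
no span is prescribed by convention, 0.75 is the `stats::loess` default)
is fitted to QC-pool intensity against injection order, evaluated at QC
orders, and carried to every injection by linear interpolation, clamped
(constant) outside the QC order range. The corrected intensity is
`raw * median(QC) / fitted`. At least 4 QCs are required; with fewer the
stage refuses to run and must be skipped explicitly. Features whose QC
intensities are all zero pass through and are logged. A fitted curve is
floored at a small positive fraction of the QC median so that a
pathological fit cannot flip intensity signs. The correction is per
feature (the standard QC-based regression approach); a global single-curve
variant was considered and rejected because drift is strongly
mass-dependent in practice.

## Quality-assurance filter

A feature is retained iff its QC coefficient of variation (sample SD over
mean, as a percentage; the n−1 denominator) is strictly below 30% and its
percentage of zeros among study injections is at most 60%. Both boundary
conventions are deliberate and tested: CV exactly 30% is removed
("below 30%" is strict), zero fraction exactly 60% is retained ("greater
than 60%" is strict). An undefined CV (QC mean 0) fails the CV rule.
Blanks are excluded from every statistic.

## Paired volcano pre-selection

Per feature, on paired per-subject values (one injection per subject per
group; extras are an error, because the crossover design has exactly one
sampled session per arm and timepoint):

* fold change: `FC = mean(b) / mean(a)` over paired subjects, after
  replacing zeros by half the feature's smallest positive value
  (configurable to a unit offset); `log2FC = log2(FC)`. Fold change is
  computed on normalized intensities.
* test choice: Shapiro-Wilk on the paired differences at level 0.05; the
  paired t-test when normality is not rejected, otherwise the Wilcoxon
  signed-rank test (exact for n ≤ 25 without ties or zeros, else the
  normal approximation with continuity correction). Constant differences
  route to Wilcoxon with a degeneracy flag; all-zero differences give
  p = 1 by convention; a constant non-zero difference gives p = 0 with a
  flag.
* multiplicity: Benjamini-Hochberg across features.
* selection: `|log2FC| > 1` (strict) and adjusted p < 0.05 (strict). The
  significance rule is applied to the BH-adjusted p-value — the stricter
  of the two defensible readings — and can be switched to raw p in the
  configuration.

Under a null simulation the joint rule selects essentially nothing: BH
bounds the false discovery rate at 5% and the fold-change filter only
removes further; the acceptance machinery measures a mean false-discovery
proportion of 0 over 100 null datasets.

## OPLS-DA and validation

The multivariate stage models only the volcano-selected features
(mirroring the pre-selection-then-projection workflow); with fewer than 2
selected features it is skipped with an explicit status, and a lone
selected variable still proceeds to annotation. Samples are the paired
injections of both groups; the response is the group label coded as a
centered ±1 dummy.

Columns are centered and unit-variance scaled by default (the convention
of the mainstream chemometrics software; Pareto and center-only are
available). PCA is computed by SVD with a deterministic sign convention
(largest-magnitude loading element positive).

OPLS-DA uses the NIPALS-type O-PLS algorithm for a single response: the
predictive weight is `w ∝ X'y` (unit norm, invariant under orthogonal
deflation); each orthogonal component takes the X-loading of the current
predictive score, removes its projection on `w`, normalizes, scores, and
deflates X; one predictive component is then fitted on the deflated
matrix. Always one predictive component (binary y). The number of
orthogonal components is chosen by forward selection over 0–3 as the
smallest count whose cross-validated Q² is within 1e-6 of the best; no
count is prescribed by the workflow being reproduced, and this rule is
deterministic and conservative.

Validation battery:

* **Q²** from stratified, seeded 7-fold cross-validation (7 folds is the
  mainstream default). Each training fold is re-centered/re-scaled and a
  sub-model fitted; `Q² = 1 − PRESS/SS_tot` with PRESS the squared
  out-of-fold errors of the coded response. Folds iterate classes in
  first-occurrence order so the assignment — and hence Q² — is invariant
  to relabeling the classes. Acceptability threshold: Q² > 0.5.
* **CV-ANOVA** after Eriksson, Trygg & Wold (2008, J. Chemometrics
  22:594–600): `F = ((SS_tot − PRESS)/d1)/(PRESS/d2)`, `d1` = components
  (predictive + orthogonal) + 1, `d2 = N − d1 − 1`, upper-tail F p-value;
  PRESS ≥ SS_tot is clamped to F = 0, p = 1. The degrees-of-freedom
  convention is documented here rather than claimed bit-exact to any
  vendor implementation; its behaviour is covered by a null-size
  simulation in the test suite, which shows the test is conservative
  under the null (rejection well below nominal — expected, since a null
  Q² is usually negative and F collapses to 0).
* **Permutation test**: class labels permuted (default 1,000 iterations),
  model and Q² refitted per iteration, add-one p-values
  `p = (1 + #{perm ≥ observed})/(1 + n_iter)`, bounded below by
  `1/(n_iter + 1)`.

## Discriminant-variable selection

VIP scores use the total-VIP convention over predictive plus orthogonal
components: `VIP_j = sqrt(p · Σ_a SSY_a (w_aj)² / Σ_a SSY_a)` with
unit-norm per-component weights and SSY_a the response variance explained
by component a. Whichever the SSY split, `Σ_j VIP_j² = p` holds exactly;
a predictive-only variant is available. Jack-knife confidence intervals
follow Martens: `SE_j² = ((G−1)/G) Σ_g (VIP_jg − VIP_j)²` over the G
cross-validation sub-models around the full-model VIP, with a
`t_{0.975, G−1}` interval.

The cascade ranks all modeled features by VIP (ties broken by feature
id), takes the first 30, and keeps those with VIP > 1, a CI not including
zero (zero-width at 0 counts as including), and two-sided fold change
`max(FC, 1/FC) > 1.2`. The two-sided reading is deliberate: clearance
effects have FC well below 1, which a one-sided `FC > 1.2` rule would
contradict. The top-30 cut precedes the filters, so at most 30 variables
are ever selected per comparison. Selected features also get a manual
peak-verification checklist (m/z, RT, QC intensity trace in injection
order) — a review artifact, not an automated peak-shape classifier.

## Annotation

Molecular formulas are parsed from Hill-style strings (underscore and
Unicode subscript markup tolerated) and summed over IUPAC monoisotopic
atomic masses. Adducts M+H, M+Na and M+H−H₂O use the charged-species
convention (proton mass, electron-corrected sodium); the atom-mass
convention differs by ~0.5 mDa and both keep every packaged reference row
within the ±10 ppm window — the choice is a documented constant, not a
fitted one. The window applies to the adduct m/z (the quantity actually
queried), not the neutral mass. All (compound, adduct) matches within
tolerance are reported, sorted by |ppm|; annotation is deliberately not
winner-takes-all because one accurate mass regularly admits several
candidates (including exact water-loss degeneracies such as C₆H₁₁NO
[M+H] vs C₆H₁₃NO₂ [M+H−H₂O]). MSI confidence: 1 standard-confirmed, 2
MS/MS match, 3 mass-only, 4 no hit.

# The synthetic-data generator

`simulate_study()` emulates the crossover design so every stage is
testable with known ground truth: intensity of feature f in study
injection i is

```
exp(baseline_f + subject_{f,s} + effect_f · 1[post] + ε) · drift(order_i)
```

followed by Bernoulli zero-censoring; QC pools are
`exp(baseline_f + ε) · drift(order_i)` without censoring (the pool is the
same material injected repeatedly; zeros in study samples are the
phenomenon the zero-fraction filter targets). Blanks are zero. The
sequence has 5 leading QCs, one QC per 6 study injections, a closing QC
and a final blank. Drift is a smooth positive trend-plus-sinusoid scaled
so max/min over the run equals 1 + amplitude.

Defaults are the emulated study conditions: 21 subjects, two arms, paired
pre/post, 500 features. Where the design gives no value, conventions were
chosen once and kept: baseline log-mean 7 and log-SD 1.2 (a wide
log-normal intensity range), between-subject log-SD 0.3 (~30% CV,
typical for plasma metabolites), residual log-SD 0.15, drift amplitude
0.3, zero rate 0.05, clearance fold change 0.46 (the magnitude reported
for creatinine removal; effects apply at the post timepoint only, so
affected features have FC < 1 by default). The generator does not emulate
correlated feature blocks (adducts/isotopes of one metabolite),
heteroscedastic noise, retention-time drift, or batch structure — so
passing tests demonstrate correctness of the statistical machinery on a
clean generative model, not robustness to all the pathologies of real
LC-MS data.

# Numerical choices and degenerate inputs

Strict inequalities at every published threshold; deterministic
tie-breaks by feature id; seeded fold assignment and permutations
(identical inputs and seed give identical result bundles); rank
exhaustion during orthogonal deflation reduces the component count with a
warning; a fold count exceeding the smaller class is reduced with a
warning; zero-variance columns are dropped (and logged) before
projection; an exactly class-orthogonal X is an error for OPLS-DA
(weights undefined) while a near-orthogonal one fits with R²Y ≈ 0.

# Problem sizes in the test suite

The statistical property tests run at deliberately moderate scales chosen
to make the checks sharp but quick: 25 null crossover datasets for
false-discovery control in the suite (100 in the acceptance script), 200
null datasets for the CV-ANOVA size check, 10⁴ replicates for p-value
uniformity, and 20 seeds for end-to-end cascade recovery with the
permutation test disabled there (the selection cascade does not consume
permutation results).

# Known limitations

* When all truly affected variables carry the same effect size, the
  volcano stage passes essentially only them into the OPLS-DA; VIP is
  normalized so that the mean squared VIP over modeled features is 1, so
  their scores cluster tightly around 1 and the strict VIP > 1 rule
  retains roughly half of them. The end-to-end recovery test in the suite
  measures exactly this (≈ 0.50 recovery at homogeneous fold change 2.5,
  with zero false selections). On real data, heterogeneous effect sizes
  and the co-modeled weaker variables spread the VIP distribution and
  soften the phenomenon; it is intrinsic to a hard VIP > 1 cut after a
  selective univariate pre-filter, not to this implementation.
* Q² and the jack-knife reuse one fold assignment; very small classes
  make both noisy.
* CV-ANOVA is approximate and conservative under the null.
* The one-injection-per-subject-per-group pairing rule is this package's
  contract; designs with technical replicates must aggregate beforehand.
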