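---
title: "Endophenotype-based plasma proteomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endophenotype-based plasma proteomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endosig)
```

## Why endophenotypes

Case-control designs against clinical AD diagnosis are contaminated by
preclinical pathology in "healthy" controls. `endosig` targets quantitative
pathology endophenotypes instead: the CSF tau/amyloid profile, amyloid-PET
status, and MCI-to-AD conversion. This vignette documents the models the
package implements, the tunable parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where more than one reasonable convention exists.

## The CSF pathology score

The endophenotype at the center of the pipeline is the discrimination-line
score

$$x = \frac{373 + 0.82\,[\mathrm{tTau}]}{[\mathrm{A\beta_{42}}]},$$

with tTau and A$\beta_{42}$ in pg/mL. The line passes through profiles where
amyloid and tau evidence balance; $x = 1$ is therefore its natural boundary
and the default of `dichotomize()`. The extreme-group design
(`select_extremes()`) does not depend on that boundary: it takes the $k$
lowest and $k$ highest scores, breaking ties by subject id so repeated runs
select identical groups. Boundary conventions are strict and documented:
a score exactly at the threshold is "low"; a CSF value exactly at a cohort
cutoff is "low pathology". Multi-center designs use per-cohort cutoffs
(`default_csf_cutoffs()`: Perugia 800/300/60, Barcelona 550/350/61, Milan
600/450/61 pg/mL for A$\beta_{42}$/tTau/pTau) and within-cohort z-scoring
(`harmonize_zscores()`), which removes center-specific assay scales by
affine standardization.

## Quantification conventions

**TMT.** Each 6-plex carries five study channels and one pooled reference
channel. Peptide intensities are converted to log2 ratios against the
matching reference peptide and each plex-channel is shifted so its median
log2 ratio is zero (`median_ratio_normalize()`, idempotent by
construction). Roll-up to molecular-weight isoforms (`rollup_isoforms()`)
offers both the median and the mean of a peptide set, because analyses are
routinely reported for both; aggregation happens on the log2 scale by
default — the error model is symmetric there and multiplicative biases
become additive — with a ratio-scale mode behind a flag. The detection
filter is computed over *plexes*, not samples, and its boundary is
inclusive: an isoform seen in exactly 80% of plexes is kept.

**Immunoassay.** The 5PL curve is parameterized as
$y = d + (a-d)/(1+(x/c)^b)^g$ with $a$ the zero-concentration asymptote,
$d$ the saturating asymptote, $c$ the midpoint, $b$ the slope and $g$ the
asymmetry; the fit is Levenberg-Marquardt least squares and inversion is
closed-form. Absorbances at or beyond an asymptote are reported as
out-of-range errors, never clamped — silent clamping would bias low- and
high-abundance tails. Intra-assay CV averages `100 * sd/mean` over
duplicate wells; inter-assay CV uses a control sample repeated across
plates.

**Outlier cleaning.** Concentrations are log10-transformed and, per
feature, values outside $[Q_1 - k\,\mathrm{IQR},\, Q_3 + k\,\mathrm{IQR}]$
with $k = 3$ are set to missing and logged. Quartiles use linear
interpolation between order statistics (R type 7); a `quartile_type`
argument exposes the Tukey-hinge alternative. Cleaning defaults to the
log10 scale — the scale the downstream statistics use — with a raw-scale
mode available. Missing values propagate as missing; there is no
imputation, and every analysis is complete-case per feature.

## The association battery

Four tests per feature: logistic regression (feature slope for the
dichotomized group, Wald p by default, likelihood-ratio optional),
Mann-Whitney U, linear regression of the continuous endophenotype on the
feature, and Spearman rank correlation. The nonparametric tests are run
unadjusted; covariates (age, sex, APOE e4, storage duration, plus
BMI/diabetes/center/batch in validation-style designs) enter the
regression models only. The Mann-Whitney "median difference" is the
difference of group medians (high minus low), not the Hodges-Lehmann
estimator. BH q-values are computed per test family across features —
reproducing the per-column q-values of a standard association table — and
`n_sig` counts tests with p below 0.05. Complete or quasi-complete
separation in the logistic model is raised as an error rather than
returning a divergent slope; in the battery such failures become `NA`
with a warning so one pathological feature cannot abort a screen.

The exact branch of the Mann-Whitney test (no ties, smaller group at most
8) is verified against full enumeration of all label assignments; the
logistic slope is verified against the closed-form log odds ratio on
random 2x2 tables.

## Pathway analysis

Isoform p-values are combined per protein by Fisher's method,
$X = -2\sum_i \ln p_i \sim \chi^2_{2k}$. Exact zeros (which can arise when
an upstream test underflows) are an error by default; a configurable floor
(`p_floor`) is available and used by the orchestrated pipeline. Combined
p-values become node scores $s = -\log_{10} p$. "Normalized p-values" is
read as exactly this transform — the single largest interpretive choice in
the module; rescaling scores to $[0,1]$ before averaging is deliberately
not done (a flag on `expand_network()` users can emulate it with monotone
transforms, and the KS statistic is invariant to them anyway).

Network expansion assigns every node with at least one measured direct
neighbor (edge confidence strictly greater than 0.4) the arithmetic mean
of its measured neighbors' scores. Measured proteins keep their own
scores by default; `overwrite_measured = TRUE` implements the alternative
reading in which interactor averaging replaces measured scores too.
Expansion never alters a measured node's score under the default, and
sub-threshold edges never change any output — both are tested invariants.

Enrichment uses the one-sided two-sample KS statistic
$D = \max_t (F_{\text{out}}(t) - F_{\text{in}}(t))$, i.e. the "in-set
scores are larger" alternative — enrichment, not mere distributional
difference. The null shuffles the score-to-gene assignment over the scored
universe, which for the KS statistic equals drawing random sets of the
same overlap size; p-values use the add-one correction
$p = (1 + \#\{D_{\text{null}} \ge D_{\text{obs}}\})/(B+1)$ so they are
never zero, with $B = 50{,}000$ by default (tests and the bundled pipeline
use $B = 2{,}000$, which bounds p from below at about $5\times10^{-4}$ —
ample for FDR at the collection sizes involved). BH correction is applied
within each collection, mirroring per-database q-value blocks. Ties in
scores are handled exactly: the ECDF difference is evaluated only at
tie-group boundaries.

## Classification panels

Features are residualized on covariates by least squares
(`glm_adjust()`; residuals are orthogonal to the covariate design),
ranked by first entry into the L1-regularized logistic path, and swept
over panel sizes with a linear-kernel SVM (cost 1.0, standardized inside
each training fold) under repeated stratified cross-validation. Per
repeat, held-out decision values are pooled into a single AUC; the curve
reports mean and SD over repeats.

The central design decision is that **the LASSO ranking is recomputed
inside every training fold**. Ranking once on the full data leaks label
information into feature selection and inflates cross-validated AUC; the
no-leakage property (null AUC within [0.45, 0.55] on 1,000 pure-noise
features) is the test that enforces the choice, and `rank_once = TRUE`
reproduces the optimistic variant for comparison. Minimal-panel selection
takes the smallest size attaining the maximal mean AUC (`rule = "max"`),
with a one-SE alternative. Operating metrics (sensitivity, specificity,
PPV, NPV) are computed from pooled cross-validated decision values at the
Youden-optimal threshold; the threshold is reported alongside.

Known limitation: with exactly duplicated informative features the L1
path is non-unique — coordinate descent activates one copy and may leave
the other at zero for the whole path, so first-entry ranking places the
second copy among the never-entering features. Elastic-net-style grouping
is out of scope.

## The synthetic-data generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes: bivariate log-normal CSF (log tTau ~ N(log 400, 0.5), log
A$\beta_{42}$ ~ N(log 700, 0.4)) with correlation `csf_corr` (default
-0.4; CSF tau and amyloid are modeled jointly so the pathology score
varies realistically); pTau as 0.2 tTau plus noise; protein effects acting
on the log10 concentration scale, with exactly `n_signal_proteins`
proteins shifted by `effect_size` residual-SD units per unit pathology
z-score with random sign; small nonzero covariate effects (so covariate
adjustment is genuinely exercised) and per-batch shifts. PET status and
conversion status are noisy functions of the same score. `simulate_tmt()`
tiles subjects into plexes of five, uses the arithmetic mean of the study
channels as the pooled reference (the composition of a real reference
pool — all samples vs per-batch — is generally unreported; the mean is
the simplest faithful stand-in and makes the noiseless identity "all
channels equal implies all ratios 1" exact), emits second molecular-weight
isoforms with probability `isoform_prob`, and drops whole isoforms per
plex with probability `plex_missing_prob`. `simulate_network()` plants a
high-confidence module over the signal proteins amid background edges and
unmeasured interactors; `simulate_gene_sets()` plants signal-loaded sets
amid uniform null sets; `simulate_elisa_plate()` generates duplicate
wells and a standard series from the forward 5PL model.

What the generator does *not* emulate: spectral-level artifacts (m/z,
retention time, isotope impurity), non-linear batch effects, plate-layout
spatial structure, longitudinal drift, and realistic protein-protein
abundance correlation beyond the planted effects. Passing tests
therefore demonstrate the statistical machinery is correct and calibrated
under the assumed data-generating process, not that any particular real
cohort satisfies those assumptions.

## Problem sizes and numerical choices in the test suite

The suite runs the calibration checks at sizes chosen to keep Monte-Carlo
error well inside the asserted bands: permutation calibration uses 1,000
null sets over a 200-gene universe at $B = 2{,}000$; battery type-I uses
1,000 null proteins at 200 subjects; the no-leakage check averages the
null CV AUC over six independent 1,000-feature, 400-subject noise
datasets (a single dataset's cross-validated AUC has Monte-Carlo spread
of about 0.05, so averaging is needed before asserting a ±0.05 band);
planted-panel recovery uses ten replicates at 200 subjects with three
features of standardized effect 1.0. Deterministic identities (5PL
round-trip, BH step-up, Fisher closed forms, pathology-score algebra) are
asserted to 1e-8 or tighter. All stochastic tests run under fixed seeds;
every generator is bit-reproducible given `(config, seed)`.
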