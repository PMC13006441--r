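---
title: "Methods: cross-system profiling of aptamer serum proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-system profiling of aptamer serum proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serumscape)
```

# The model and its assumptions

serumscape analyzes case–control aptamer affinity-proteomics data:
a samples × aptamers matrix of positive relative-fluorescence intensities,
vendor-normalized upstream (hybridization calibration and median
normalization are out of scope — data arrives normalized). All modelling
happens on the log2 scale; the working model for each aptamer *g* is

$$\log_2 y_{ig} = \beta_{0g} + \delta_g\,\mathrm{ME}_i
  + \boldsymbol\beta_g^\top \mathbf{x}_i + \varepsilon_{ig},
  \qquad \varepsilon_{ig} \sim N(0, \sigma_g^2),$$

with covariates $\mathbf{x}$ = (sex, age, BMI, overnight fasting), group
coded ME = 1 / HC = 0, sex F = 1 / M = 0, fasting TRUE = 1, age and BMI
unscaled (the group coefficient is invariant to covariate scaling). The
group coefficient $\delta_g$ is the covariate-adjusted log2 fold change.
Key assumptions: approximate log-normality of intensities, a shared linear
covariate structure, and exchangeability of residual variances across
aptamers for the empirical-Bayes step.

## Variance moderation

Residual variances are shrunk toward a scaled inverse-χ² prior
$(d_0, s_0^2)$ estimated by moment matching: the mean and variance of
$\log s_g^2$ are equated to their digamma/trigamma expressions under the
scaled-F sampling model, with the trigamma inverted by Newton iteration.
The moderated statistic $t_g = \delta_g / (\tilde s_g c_g)$, with
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and $c_g$ the
design-based unscaled standard error, is referred to $t_{d_0 + d_g}$.
Limits are honored exactly: $d_0 = 0$ reproduces the OLS t; $d_0 = \infty$
(declared whenever the spread of $\log s^2$ does not exceed its sampling
component) pools to $s_0^2 = \overline{s^2}$, so identical variances give
$\tilde s^2 = s^2$ — the fixed point the moment estimator must respect.
Trend and robust variants are deliberately not implemented.

## Multiple testing and classifier metrics

Benjamini–Hochberg is applied across all aptamers in one family per
analysis (not per panel): $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, capped
at 1. The per-aptamer "univariate logistic regression AUC" is realized by
the rank (Mann–Whitney) equivalence — any monotone score yields the same
ROC area — which removes iterative-fit nondeterminism; the operating point
maximizes Youden's J with ties broken toward higher specificity. Scores
are oriented by the estimated direction of change before computing the
operating point.

# QC choices

"PCA on Mahalanobis distances" is ambiguous as a recipe; the package fixes
the order as: log10 transform, center, project onto the first $k$
components ($k$ = smallest number explaining ≥ 90% of variance, capped at
$n-2$), then $d^2$ with per-component variances. Under approximate
normality $d^2 \sim \chi^2_k$ in the retained score space, which is what
justifies the stated χ² test (flag at p < 0.1). The 90% target is a
config parameter because no component count is canonical.

Leverage masking uses column z-scores on **raw** intensities at the stated
cutoff ±1.8 (note: ±1.8 is *not* the normal 2.5th/97.5th percentile — that
would be ±1.96 — but the numeric cutoff is taken at face value). Masked
cells are imputed with the remaining column minimum (low side) or maximum
(high side). This scheme is **not strictly idempotent**: replacing
extremes with in-range min/max shrinks the column sd, so a second pass can
re-flag boundary cells. The cell-level report therefore always carries the
full imputation log, and the tests assert the report rather than
idempotence. Sample mean/sd (n−1) conventions are used throughout, and
sample-outlier removal precedes z-scoring.

# Duplicate-aptamer resolution

Proteins are keyed on gene symbol; aptamers without a symbol pass through
unmerged. Directional consensus is the majority-sign fraction among an
aptamer family's nonzero log2FCs (zero counts toward neither sign),
inclusive at 0.8. The decision tree is: (1) singleton → itself;
(2) consensus → min-p among majority-sign aptamers; (3) no consensus,
exactly one significant (p < 0.05) aptamer → that one; (4) several
significant, same sign → min-p among them; (5) significant aptamers of
opposite sign → overall min-p with a `mixed` flag. Ties on p break by
larger |log2FC|, then lexicographic id, making resolution order-invariant.
Min-p (rather than a combined statistic) is asserted as the merge rule;
paths are logged so alternative trees can be audited. Correlation
category boundaries are lower-bound-inclusive for the upper class, so
|r| = 0.3 is "moderate" and |r| = 0.8 "very strong".

# Compartment skew statistics

The KS/HL comparison population is the **class versus the complement of
all assigned aptamers**, on covariate-adjusted per-aptamer log2FCs (not
per-sample values): D ≈ 0.08 at p ≈ 1e−14 is only attainable with
thousands of observations per side, which identifies aptamer-level fold
changes as the intended inputs. A protein-level variant (post-dedup) is a
flag. The KS p uses the asymptotic Kolmogorov distribution at
$\sqrt{n_{\mathrm{eff}}}D$ with $n_{\mathrm{eff}} = n_x n_y/(n_x+n_y)$;
at n = 5 + 5 it differs from the exact enumeration by up to ~0.1–0.2,
which the tests document. The Hodges–Lehmann CI takes symmetric order
statistics of the sorted pairwise-difference set at the normal-approximate
Mann–Whitney ranks. Percentages are rounded half-up to one decimal (base
R's banker's rounding would print 36.1 where 36.0 is correct for 62/172).

# Association network and cross-platform choices

Semi-partial correlations remove the covariates from the **aptamer side
only** (the cited convention of partial-correlation packages); the
orientation is a logged flag since it is not canonical. Metabotype enters
as an M1 indicator. Communities are defined combinatorially — each
network aptamer's label is its exact set of connected clinical variables —
so Venn counts recompute from labels by construction. Enrichment is
hypergeometric over-representation (upper tail, `P(X ≥ k)`); preranked
GSEA is a non-goal.

Cross-platform concordance gives "mixed" precedence: a protein whose own
aptamers disagree in sign is mixed even if one aptamer matches the
immunoassay. Directions are covariate-adjusted log2FC signs; restricting
to nominally significant aptamers is available behind
`significant_only` (default off, logged). The low-abundance filter drops
analytes with missing fraction strictly above 0.5 (an analyte at exactly
50% is retained).

PERMANOVA permutes labels freely (no strata); exact enumeration is
available for two groups and is used by the oracle tests. PCA is
covariance PCA on centered, unscaled log2 data with a deterministic sign
convention (largest-magnitude loading positive). Variance partitioning
uses fixed-effects drop-one R² rather than the mixed-model formulation of
the variancePartition package: the categorical covariates here are
binary, and fixed-effects increments are deterministic and auditable —
a documented method substitution. Printed envfit-style loadings in the
source literature exceed unit-correlation bounds for some rows, so the
package defines its own normalization (unit direction cosines + r²) and
does not assert equality with those triplets.

# The synthetic-data generator: what it emulates, and what not

`generator_config()` defaults state the cohort the analysis was designed
around: 50 ME / 29 HC; ~6,400 proteins on ~7,300 aptamers with ~12% of
proteins carried by two aptamers; subcellular class shares
53.4/25.9/17.6/3.0%; class-conditional log2 group shifts with means −0.3
(intracellular), +0.15 (membrane classes), +0.3 (secreted) and sd 0.15,
drawn **per protein** and shared by duplicate aptamers (which is what
makes directional concordance a property rather than an accident);
covariates age ~ N(40, 10), BMI ~ N(24, 4) truncated, sex ~
Bernoulli(0.77 female), fasting confined to ME at rate 0.22; residual sd
0.3 on the log2 scale; SF-36PF ~ N(31.2, 19.3) and steps ~ N(3021, 2001)
for ME only. Where the source gives no value (per-aptamer covariate slope
sds, panel membership rate 0.03, secretome category weights), values were
chosen once at what a practitioner would call realistic magnitudes and are
not revisited.

Duplicate aptamers mix noise as
$\sqrt\rho\,\mathrm{common} + \sqrt{1-\rho}\,\mathrm{own}$, giving
expected pairwise Pearson correlation exactly ρ when no other shared
signal is present. (A mixture weighted ρ/√(1−ρ²) — sometimes quoted for
this purpose — yields pairwise correlation ρ², which fails its own
calibration target; the square-root weighting is the package's corrected
choice.) Injected outlier samples are each displaced by the configured
log10 magnitude on their **own** random half of the aptamers — distinct
corrupted samples rarely share a corruption direction, and per-sample
directions are also what makes PC-space detection well-posed for k > 1.
The cross-platform replicate is the per-protein mean log2 consensus plus
platform noise; planted discordance mirrors the ME−HC difference of a
Bernoulli-selected analyte subset.

What the generator does **not** emulate: plate/batch effects,
hybridization chemistry, heteroskedastic aptamer noise, non-normal tails,
metabotype-linked effect structure, or missingness in the aptamer matrix.
A green test therefore establishes correctness of the statistical
machinery under the stated model — not robustness to assay artifacts.

# Numerical and degenerate-input conventions

* Missing tokens on input: `""`, `"NA"`, `"NaN"`; anything else
  non-numeric is a hard error with cell coordinates.
* Tables are written with `%.17g`, which round-trips doubles exactly;
  the loaders keep numeric columns as parsed (no string round trip).
* Zero-variance columns: no leverage masking; correlation pairs skipped
  with a warning; constant covariates skipped by envfit with a warning.
* Welch test with two zero-variance equal-mean groups returns p = 1.
* PERMANOVA permutation p has floor 1/(B+1); exact enumeration divides by
  the number of distinct assignments (no +1), matching complete-coverage
  inference.
* Seeds: the pipeline derives per-stage child seeds by stable string
  hashing of stage names below 2³¹, so stage toggles do not shift the
  random streams of other stages.

# What the tests establish

The acceptance suite covers: the ten printed percentage worked examples
(exact); type-I error calibration on 100 global-null datasets (mean
p < 0.05 fraction within 0.05 ± 0.01, BH family discoveries near zero);
recovery of the planted compartment skew (KS p < 1e−6, HL signs with CIs
excluding 0 in ≥ 90% of 20 runs at ~3,000 aptamers); oracle equivalences
(PERMANOVA hand decomposition F = 200, p = 1/3; KS ECDF enumeration;
HL pairwise enumeration; brute-force hypergeometric; BH step-up by hand);
≥ 95% recovery of injected outlier samples; moderation-prior recovery
within stated tolerances; the cross-platform zero-noise/flip construction;
and order-invariance of duplicate resolution. Independent oracles in the
module tests include `stats::p.adjust`, `stats::t.test`,
`stats::ks.test`, `stats::wilcox.test`, `limma::squeezeVar`,
`vegan::adonis2`, per-aptamer `lm()` fits, and combinatorial enumeration.

# Known limitations

Cohort-scale results (e.g. counts of affected aptamers in the thousands,
PERMANOVA statistics of a specific cohort) require the deposited study
data and are not reproduced at desk scale. The moderated model assumes a
single variance prior across all aptamers; the network stage computes all
aptamer–variable correlations and filters (the "relevant subsets" of the
source are not further specified, so counts are logged instead). An
`.adat` reader is a documented extension point, not implemented.
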