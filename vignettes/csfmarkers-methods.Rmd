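---
title: "Models and methods behind csfmarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind csfmarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfmarkers)
```

`csfmarkers` analyses longitudinal dual-platform (TMT + LFQ) CSF proteomics
for treatment-response biomarkers. This vignette explains the statistical
models, the tunable parameters and their defaults, what the synthetic
cohort generator does and does not emulate, and the numerical and design
choices that were genuinely open.

## The data model

Each platform delivers a proteins × samples raw intensity matrix with
missing entries; sample metadata maps samples to patients, visit months
(default schedule 0, 2, 10, 18, 26, 34, 42) and TMT plex; a clinical table
carries the HFMSE motor score (0–66) and routine CSF chemistry per
patient-visit. Missing measurements are `NA` in memory and empty cells on
disk — never a numeric sentinel — because downstream imputation must
distinguish "not detected" from zero.

## Preprocessing

**Sample filter.** TMT samples whose summed non-missing intensity falls
below a threshold (default 225, in the dataset's arbitrary units) are
removed. The threshold is configuration, not science: its scale depends on
the instrument's intensity units.

**Detection filter.** A protein is kept iff some patient detected it in at
least `min_within_patient` (= 2) samples *and* at least `min_patients`
(= 2) patients detected it at all. TMT and LFQ are filtered independently,
since they are processed as separate datasets throughout.

**Variance-stabilizing transformation.** Raw intensities follow a
multiplicative-plus-additive error model, so per-protein SD grows with the
mean. The transform is (1) per-sample calibration `b_s · x` with
`b_s = median_ref / median_s` — a purely multiplicative gain correction.
Instrument gain acts multiplicatively; an additive raw-scale offset (as a
naive median/MAD affine alignment would produce) shifts the low-intensity
range into or out of the additive-noise floor and can visibly distort, even
invert, the mean–variance trend. After calibration all sample medians agree
exactly. (2) The generalized log
`glog2(x) = log2((x + sqrt(x² + λ²))/2)`, which is `log2(x)` for
`x ≫ λ` and linear near zero. λ is selected to minimize the absolute
Spearman correlation between per-protein mean and SD: a coarse grid over
quantiles of the calibrated intensities, then — because the correlation
increases monotonically through zero in λ — log-space bisection of the
sign change. A plain grid is too coarse: the crossing occupies a narrow
quantile band. Differences on the result scale are log2 fold changes.

**Imputation.** For a missing entry `(p, s)`, the k = 10 proteins observed
at `s` whose profiles co-vary most closely with `p` are combined by
inverse-distance weighting. Each candidate `q` gets an intercept
`offset_q = mean(x_q − x_p)` over the samples both proteins observe, the
distance is the RMS of the offset-adjusted differences, and the imputed
value is the weighted mean of `x_q[s] − offset_q`. The offset adjustment
matters: protein abundances span ~20 log2 units, so a raw Euclidean
distance ranks neighbours almost purely by abundance proximity, which
carries no information about sample-specific deviations — a kNN built on it
cannot beat protein-mean imputation. Matching on co-variation lets
co-regulated proteins supply the patient- and sample-specific signal. Two
identical profiles have distance zero, so a twin's value is copied exactly.
Ties are broken by protein ID; proteins with fewer than k usable neighbours
fall back to their observed mean; observed entries are never altered.

Imputed matrices feed the downstream tests as if observed. This follows the
impute-then-test convention of the field's standard pipeline; it slightly
understates residual variance when missingness is high, which is why the
package verifies false-discovery control empirically on null simulations
rather than assuming it.

## Patient adjustment and sample correlation

Per protein, OLS on `~ 0 + timepoint + patient` (all timepoint indicators,
patient indicators with one dropped) and subtraction of only the fitted
patient component — centred so protein means are preserved. Because
timepoint indicators are retained during fitting, treatment signal is not
absorbed: timepoint contrasts before and after adjustment agree to
numerical precision, and the operation is idempotent. Adjusted rows are
z-scored (sample SD, n − 1), samples are correlated (Pearson) and clustered
agglomeratively on `1 − r`. The linkage is average — the heatmap default in
this field — and configurable; platforms are clustered separately by
default since the joint-versus-separate choice is not dictated by the
design.

## Differential expression

Per-protein OLS on the same patient-blocked design gives `β̂`, residual
variance `s²` and df `d`. Variances are moderated toward a scaled
inverse-χ²(d₀, s₀²) prior estimated from the first two moments of
`log s²`: with `e = log s² − ψ(d/2) + log(d/2)`,
`var(e) = ψ′(d₀/2) + ψ′(d/2)` and `mean(e) = log s₀² + ψ(d₀/2) − log(d₀/2)`;
the trigamma equation is inverted by Newton iteration. When the spread of
`log s²` does not exceed chi-square sampling noise the prior is degenerate
(d₀ = ∞) and every posterior variance equals the geometric mean of the
observed variances — in that limit, and when d₀ is forced to 0, the
moderated *t* coincides exactly with the classical *t*, a property the
tests assert. Posterior variances
`s²_post = (d₀ s₀² + d s²)/(d₀ + d)` yield
`t = c′β̂ / sqrt(s²_post · c′(X′X)⁻¹c)` on `d₀ + d` df for every pairwise
timepoint contrast, oriented later-minus-earlier so upregulation under
therapy is positive. BH runs across proteins within each contrast (a
global mode is exposed; the within-contrast scope mirrors the reference
implementation). DEPs require FDR < 0.05 *and* |log2FC| > 0.5, both strict,
as printed.

## Cross-platform and response-marker analytics

Overlap, rank-intensity and top-k rank trajectories are set arithmetic and
deterministic ranking (ties by protein ID). The cross-platform DEP
intersection demands a same-direction DEP flag in the *same* contrast on
both platforms (strictest reading; an any-contrast mode is available);
conflicting directions are reported separately, never silently merged.

Consistency scores use the TMT data and the cross-platform DEP directions
as reference signs: per protein and post-baseline visit, the fraction of
patients (with data at baseline and that visit) whose change has the
reference sign; a change of exactly zero counts against consistency.

The change–change screen joins per-patient Δprotein (visit minus baseline)
with ΔHFMSE on (patient, visit) and computes Pearson *r* with
`t = r·sqrt(n−2)/sqrt(1−r²)`. Baseline pairs are identically zero and are
excluded by default (an inclusive mode exists for exact replication of
counts). Both raw and BH-adjusted p values are reported, since the original
analysis reports exact p values without stating an adjustment. A caveat the
simulations make visible: the pooled pairs are clustered within patient
(the baseline measurement error is shared by all of a patient's deltas), so
the effective sample size is smaller than the pair count and the null
spread of *r* is wider than the nominal t distribution suggests; rankings
are robust to this, individual p values are mildly optimistic.

Cutoff rules classify a patient-visit as improved-or-stable when
Δprotein ≥ θ and as not-improved-or-worse when Δprotein ≤ −θ, abstaining in
between; the observed class is ΔHFMSE ≥ 0. A zero HFMSE change satisfies
both clinical phrasings, so it is assigned to improved-or-stable — the
reading consistent with pairing "improvement or stability" with an
intensity increase — and this choice is a flagged decision, not a claim
about the original analysis. `scan_cutoffs()` maximizes concordance over a
grid subject to a minimum non-abstained fraction (default 25%), ties to the
smaller θ. Concordance uses only the sign of ΔHFMSE and is therefore
invariant to any strictly increasing transform of the score.

Enrichment of a hit set against a background over user-supplied term
annotations is the one-sided hypergeometric upper tail with BH across
terms; no ontology semantics are bundled.

## The synthetic cohort generator

`simulate_cohort()` draws raw intensities as
`2^(μ_p + patient + plex + effect) · 2^ε_mult + ε_add`, so the
multiplicative component makes raw SD grow with the mean and the additive
floor (SD 400 on baselines spanning 2^10–2^30) makes the glog the right
stabilizer. Key defaults and why:

* **Design**: 24 patients, 7 visits with the study's dropout counts
  (24, 24, 24, 20, 17, 14, 11); 1,674 TMT proteins, 441 LFQ proteins, 429
  shared — the shared set is the top of the TMT abundance range, plus one
  dominant albumin-like protein pinned above everything.
* **Heterogeneity**: protein-specific patient effects (SD 0.5 log2) with
  half their variance shared within 25 protein modules — co-regulation is
  what makes neighbour-based imputation informative at all. TMT plex
  effects (SD 0.25 log2) are protein-specific, and samples are randomized
  across plexes, the standard isobaric block design; a patient-ordered plex
  layout would alias plex effects onto timepoint contrasts.
* **Treatment structure**: a broad compositional drift (half the proteins
  get a persistent shift, SD 0.5 log2, from the first on-treatment visit) —
  calibrated so pre-treatment samples separate cleanly in the correlation
  heatmap, as the study observed; 40 planted DEPs at |log2FC| = 1.5 from
  month 10; 10 clinically coupled proteins whose intensity tracks ΔHFMSE at
  0.2 log2 units per point — calibrated so planted markers top the screen
  the way the study's marker pair did.
* **Clinical**: HFMSE baseline ~ round(N(23, 15)) truncated to [0, 66]
  (the reported ±3.9 is a standard error, so the SD is a design choice);
  mean drift (0, 1.1, 2.2, 1.6, 1.4, 2.6, 2.1) per visit plus patient-level
  response (SD 2) and visit noise (SD 2). qAlb, lactate, glucose and
  lymphocyte percentages couple negatively to ΔHFMSE, macrophages
  positively, total protein not at all.
* **Missingness**: 10% missing-at-random by default; an
  intensity-dependent logistic mechanism is available, with its intercept
  calibrated so the overall rate still matches.

What the generator does **not** emulate: peptide/PSM-level quantification,
reporter-ion interference and ratio compression, fractionation artifacts,
left-censored (MNAR) missingness, protein-inference discrepancies between
platforms, and real biological covariance beyond the module structure.
Passing tests therefore demonstrate correctness of the statistical
machinery under a plausible generative model, not performance on any real
cohort.

## Numerical choices and degenerate inputs

* λ search: 20-point quantile grid plus sign-change bisection (30
  iterations, geometric midpoints); λ = 0 is admitted only when all
  calibrated values are positive.
* Trigamma inversion: Newton with asymptotic closed forms outside
  [1e-7, 1e7].
* Contrast estimates below 1e-12 are treated as exactly zero (t = 0,
  p = 1); zero posterior variance with a nonzero estimate gives t = ±Inf.
* Constant proteins cannot be z-scored and are dropped with a warning;
  zero-variance features are skipped (and logged) by the correlation
  screen; a protein with no observed values is an imputation error naming
  the protein; a design with patients confounded with timepoints is
  rejected with the aliased columns listed.
* All ranking and neighbour ties break by protein ID, so every stage is
  deterministic given (configuration, seed).

## Problem sizes used by the test suite

The packaged checks run on scaled-down cohorts chosen as the package's own
test design: oracle-equivalence properties use 100 random small instances
per statistic; null false-discovery control uses 20 null cohorts of 500
proteins, 12 patients, 5 visits; recovery uses 5 cohorts of 500 proteins
and 12 patients on the full 7-visit schedule with proportional dropout;
transformation and imputation quality use 5 cohorts of 300 proteins; the
end-to-end structural check runs one full-size default cohort. The
acceptance script (`scripts/acceptance.R`) recomputes all headline
quantities at these sizes from a single command-line seed.

## Known limitations

* Impute-then-test understates residual variance at high missingness; FDR
  control is verified empirically at the default 10% rate, not guaranteed
  at arbitrary rates.
* The pooled change–change screen ignores within-patient clustering (by
  design, matching the original analysis); treat its p values as a ranking
  device.
* Plex effects are simulated and tolerated but not explicitly modelled in
  the DEP design, again matching the analysis being implemented; severely
  unbalanced plex layouts would require adding a batch term.
* Cutoff rules are descriptive classifiers on observed cohorts; they are
  not validated predictors.
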