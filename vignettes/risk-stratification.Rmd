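---
title: "Triage of nonvariceal upper-GI bleeding with the Glasgow-Blatchford score and nasogastric aspirate"
author: "gbsnga"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of nonvariceal upper-GI bleeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsnga)
```

## The clinical problem

Emergent endoscopy benefits patients with a high-risk endoscopic lesion
(HREL): a peptic ulcer with spurting (Forrest Ia) or oozing (Ib) bleeding
or a non-bleeding visible vessel (IIa), or an actively spurting non-ulcer
source. Most patients endoscoped for suspected upper-GI bleeding do not
have one. The Glasgow-Blatchford score (GBS) — an integer 0–23 built from
blood urea nitrogen, hemoglobin, systolic blood pressure, pulse, melena,
syncope, hepatic disease and cardiac failure — is the standard admission
risk score, but its safe rule-out (GBS = 0, sometimes ≤ 1 or 2) covers
only a small fraction of presentations.

The rule evaluated here adds one bedside observation: the appearance of
the nasogastric aspirate (NGA), recorded as bloody, coffee-ground,
bile-like or clear and binarized to bloody vs non-bloody. A patient is
**low-risk** exactly when the aspirate is non-bloody *and* GBS ≤ *t*;
everyone else is a candidate for emergent endoscopy. For ROC analysis the
rule is written as a continuous score

$$S \;=\; \min(\mathrm{GBS} + 23\cdot[\text{bloody NGA}],\; 23),$$

so a bloody aspirate forces the maximal score; `classify_patient(g, nga, t)`
is identical to `combined_score(g, nga) <= t` for every `t` ≤ 22 (a
property the test suite verifies exhaustively). A threshold of 23 is
rejected by construction: it would place bloody-aspirate patients in the
low-risk group, which the cap exists to prevent.

## Reconstructing the development cohort

The 115-patient development cohort is not deposited anywhere, but its
*entire* joint distribution of (GBS, bloody NGA, HREL) is identified by
two published cumulative tables plus one pair of counts:

* the rule-out table of the GBS over all patients (cumulative counts of
  patients with score ≤ k, by HREL status, k = 0..17);
* the same table for the combined score, whose rows below 23 can only
  contain non-bloody patients (bloody patients all score 23);
* the bloody-aspirate counts by HREL status (24 with, 11 without).

First differences of the first table give per-score counts for all
patients; first differences of the second give them for non-bloody
patients; subtraction yields the bloody patients' GBS distribution per
stratum. `reconstruct_cohort()` materializes one record per patient,
deterministically ordered (HREL first, bloody first, GBS ascending, ids
`P001`–`P115`), and rejects inconsistent tables (any negative difference).
Re-aggregating the records reproduces the input tables bit-for-bit. All
patients have GBS ≤ 17 because both tables reach their totals there.

```{r recon}
coh <- study_cohort()
c(n = nrow(coh), with_hrel = sum(coh$hrel))
round(c(mean(coh$gbs[coh$hrel]), mean(coh$gbs[!coh$hrel])), 1)
```

Row labels in the published table carry typographic artefacts
("2≤2", "3≤3", "4≤4"); they are read as ≤ 2, ≤ 3, ≤ 4 — the only
interpretation under which the columns are non-decreasing — and the
shipped TSV keeps the numeric cutoffs only.

## Statistical machinery

**Scoring.** `compute_gbs()` applies the original integer-banded
criteria, with bands closed on their printed endpoints (BUN exactly
6.5 mmol/L scores 2; hemoglobin exactly 120 g/L in a man scores 1). BUN in
mg/dL is converted by the molar factor 2.8. Hemoglobin is handled in g/L
internally and g/dL in the CSV dialect (clinical reports of ~8 "mg/dl" for
hemoglobin are read as g/dL; the mg/dL value would not be physiologic).

**ROC.** `empirical_auc()` is the tie-corrected Mann-Whitney estimator,
computed through DeLong placement values: the placement of a case is the
fraction of controls it beats, ties counting one half. Integer scores are
heavily tied, so the half-tie convention matters: on the reconstructed
cohort the GBS AUC is exactly 1790/2800 = 0.639. Variance is
$S_{10}/m + S_{01}/n$ (sample variances of case and control placements), the
CI a normal approximation truncated to [0, 1] (the published CIs,
0.532–0.747 and 0.788–0.921, reproduce to 3 decimals).
`delong_paired_test()` adds the placement covariance for correlated
curves; identical scores return z = 0, p = 1 by convention. Scores are
oriented higher-is-worse; no automatic direction flipping is done.

**Threshold selection.** `threshold_sweep()` tabulates cumulative
rule-out counts and the sensitivity/specificity of "high-risk iff score
> k"; `select_optimal_threshold()` picks the *largest* cutoff with
sensitivity ≥ 98%, an asymmetric criterion chosen because missing a
patient who needs endoscopic therapy is far costlier than one unnecessary
endoscopy. On the development cohort this yields GBS ≤ 0 and combined
score ≤ 9.

**Accuracy metrics.** `diagnostic_metrics()` reports sensitivity,
specificity, PPV and NPV with exact Clopper-Pearson 95% CIs (beta
quantiles; lower bound exactly 0 at 0/n, upper exactly 1 at n/n). The
conventional definitions are used throughout; note that the published
performance table prints its PPV/NPV columns in the opposite orientation
(its "NPV" of 31.2% for the GBS ≤ 0 rule is the conventional value of
tn/(tn+fn) for the *complementary* labelling; the conventional NPV of that
rule-out is 3/3 = 100%). The package does not reproduce the transposed
orientation.

**Group comparisons.** Means are compared with the pooled-variance
Student t-test and proportions with the chi-square test without continuity
correction (only significance bounds are published; the uncorrected form
is the simpler default) or Fisher's exact test.

**Reclassification.** The published analysis reports continuous NRI and
IDI but not how scores were mapped to risks, and the figure carrying the
numeric values is not machine-readable; these statistics are therefore
property-tested (zero on identity, antisymmetry, bounds, and a hand-
enumerable score-based NRI of 24/35 − 11/80 ≈ 0.548 on the cohort) rather
than value-matched. `compare_reclassification()` calibrates each score
with a univariate logistic fit (`calibrate_risk()`); under perfect
separation the fit is flagged and rank-based pseudo-risks
`rank(score)/(n+1)` — which preserve the ordering, all that NRI uses — are
substituted. A `raw_scores = TRUE` mode computes score-based NRI/IDI
directly. Bootstrap CIs resample patients with replacement under a fixed
seed, redrawing any resample that loses an outcome class.

## Rounding convention

Printed percentages in the source tables follow round-half-to-even at one
decimal (13/80 → 16.2, 33/80 → 41.2, 21/80 → 26.2), i.e. R's `round()`;
the package uses the same convention in its report tables, and every
sensitivity/specificity cell of the published sweep then reproduces
exactly.

## The synthetic-data generator

`generate_cohort(synth_config(...))` emulates the features of the study
population that the method touches, with defaults fixed at the
development-cohort values:

| parameter | default | meaning |
|---|---|---|
| `prevalence_hrel` | 35/115 (30.4%) | P(HREL) |
| `p_bloody_given_hrel` | 24/35 (68.6%) | P(bloody NGA \| HREL) |
| `p_bloody_given_no_hrel` | 11/80 (13.8%) | P(bloody NGA \| no HREL) |
| GBS, HREL stratum | N(11.3, 3.7²) discretized to 0..23 | score distribution |
| GBS, no-HREL stratum | N(9.4, 4.2²) discretized to 0..23 | score distribution |
| `p_male` | 73/115 | sex mix (hemoglobin criteria) |

By default the GBS is drawn independently of aspirate status within each
outcome stratum — the simplest model matching the published marginals. The
real data are not independent in this way (bloody and non-bloody patients
differ in GBS), which shifts the combined-score AUC; when the full joint
matters, pass empirical per-(stratum × aspirate) weights
(`gbs_distribution = list(type = "empirical", weights = ...)`), under
which a 10⁵-patient cohort recovers both AUCs to within ±0.02.

Raw clinical variables are then generated *backwards* from each target
score: one component-point decomposition is drawn uniformly from the
exhaustive enumeration (`gbs_decompositions()`; every total 0–23 is
feasible for either sex, and 23 has a unique decomposition), and each raw
value is drawn uniformly on a measurement grid inside the band awarding
those points (integer mmHg and beats/min, 1 g/L hemoglobin, 0.1 mmol/L
BUN). Open-ended bands use bounded physiologic surrogates (BUN ≥ 25 drawn
in [25, 60] mmol/L, SBP < 90 in [60, 90), pulse ≥ 100 in [100, 140], and
so on — see the band constants in the source). The grid guarantees that
CSV rounding can never move a value across a band edge, so
`compute_gbs()` on the generated raws returns the target score exactly,
for every patient. Age, diastolic pressure, hematemesis and the concrete
non-bloody aspirate category are sampled independently, only for realism
of the CSV; they enter no score.

What passing tests on synthetic cohorts do **not** show: the generator
contains no covariate correlations (age, medication use), no
miscalibration of the GBS inputs, and — by default — none of the
GBS-aspirate dependence of real patients, so it validates the machinery,
not the clinical transportability of the rule.

## Problem sizes and determinism

The test suite works at the natural scales of the problem: the 115-patient
reconstruction everywhere, exhaustive enumeration over all
score × aspirate × threshold combinations for the classifier equivalence,
random cohorts up to n = 200 against the brute-force pairwise AUC oracle,
a 4000-resample stratified bootstrap as an independent check of the DeLong
test on a 20-patient set, and 10⁵-patient synthetic cohorts for parameter
recovery. All randomness is seeded; `generate_cohort()` is
byte-reproducible given its seed and restores the caller's RNG state.

## Limitations

* The development cohort is single-center and modest (115 patients; 35
  events); the ≥ 98% sensitivity floor is attained here with sensitivity
  exactly 100%, and wider data could move the selected cutoffs.
* The reconstruction recovers (GBS, aspirate, outcome) exactly but no
  other covariates; covariate columns in the shipped fixture are absent,
  not imputed.
* Published NRI/IDI values are not machine-readable, so reclassification
  statistics are verified by properties and oracles only.
* The rule is for *nonvariceal* bleeding; suspected variceal bleeding was
  excluded from the development data and is out of scope.
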