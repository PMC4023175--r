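---
title: "Heart-rate-dynamics risk models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate-dynamics risk models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvrisk)
```

## The problem

After acute myocardial infarction, autonomic dysfunction — depressed vagal
modulation of the sinus node — marks patients at elevated risk of cardiac
death. Individual Holter-derived indices each read one facet of that
dysfunction: SDNN summarizes total variability, deceleration capacity (DC)
isolates vagally mediated decelerations, heart-rate turbulence reads the
baroreflex response to a ventricular ectopic beat, and LVEF is not an
autonomic measure at all. `hrvrisk` implements the integrated approach:
extract the full set of heart-rate-dynamics features from each 24-hour
recording and let a support-vector machine combine them into a single risk
score, evaluated patient-by-patient with leave-one-out cross-validation and
compared against the single-index classifiers on ROC terms.

The original cohort behind this methodology (208 analyzable recordings, 196
survivors, 12 cardiac deaths over ~28 months) is not publicly deposited, so
the package pairs the analysis stack with a synthetic-cohort module that
reproduces the *published statistical structure* of that cohort. Everything
downstream is therefore testable, but no synthetic result should be read as
a reproduction of the clinical AUCs.

## Preprocessing

Recordings arrive as beat-per-row annotation files (onset time in ms, RR
interval in ms, beat label `N`/`V`/`A`/`X`). Validation enforces positive
intervals, known labels, monotone onset times and time/interval consistency
within one sample of the 128 Hz digitization (1/128 s); the first offending
file line is named in the error.

* **Sinus-coverage gate.** Recordings whose sinus (`N`) beats cover less
  than 80% of total recording time are rejected, mirroring the enrolment
  exclusion rule. The threshold is configurable; the gate is monotone in it.
* **NN extraction.** Interval *i* is normal-to-normal iff beats *i* and
  *i − 1* are both `N`. The filter is idempotent and an all-ectopic series
  yields an empty NN series, not an error.
* **5-minute segmentation.** SDANN/ASDNN need segment boundaries. The
  segment length is never stated alongside the index definitions in the
  source methodology, so the package adopts the Task Force standard 300 s
  window, cut by cumulative NN time. A final partial window is kept iff it
  is at least half full (≥ 150 s of NN time) — under-filled tails otherwise
  dominate the per-segment SD with noise while recordings with gaps remain
  analyzable.

## Time-domain indices

All SDs use the population convention (divide by *n*); at 24-h recording
lengths the choice is clinically immaterial, but it pins down exact unit
tests. The triangular index divides the NN count by the modal bin count of
the NN histogram with bins of 1000/128 = 7.8125 ms anchored at zero — the
discretization implied by the 128 Hz recording hardware. Mean heart rate is
reported in beats/min as 60000 / mean NN: the published per-class values
(68.4 and 73.5) are plainly per-minute even though the accompanying text
says "per hour", and this package follows the numbers.

## Heart-rate turbulence

Turbulence is measured per VPC episode. The source methodology states that
turbulence was computed but not its formulas; the package follows the
standard turbulence methodology it cites:

* **Eligibility.** An episode needs two clean sinus intervals before the
  coupling interval, a coupling interval ≤ 80% of the reference (mean of
  the two pre-ectopic intervals), a compensatory pause ≥ 120% of it, 15
  post-pause sinus intervals, all window intervals within 300–2000 ms, and
  no other non-sinus beat in the window. One eligible episode suffices (no
  minimum count is imposed).
* **Onset** `TO = 100·((RR₁+RR₂) − (RR₋₂+RR₋₁))/(RR₋₂+RR₋₁)`, averaged over
  episodes. Post-ectopic shortening (the physiologic early acceleration)
  gives TO < 0.
* **Slope.** The post-ectopic tachograms are averaged beat-position-wise
  *before* regression (the standard convention; the alternative —
  per-episode slopes, then averaging — is more noise-sensitive because each
  per-episode value is already a maximum over 11 windows). TS is the
  maximum least-squares slope over the 11 runs of 5 consecutive values in
  the first 15 averaged intervals.

Recordings without eligible ectopy have no turbulence value (`available =
FALSE`, TO/TS `NA`). In the original cohort 83 of 208 recordings had no VPC;
features that can be missing are excluded from classifiers rather than
imputed, so no model configuration contains TO or TS.

## Phase-rectified signal averaging

Deceleration anchors are NN positions that lengthen relative to their
predecessor; increments above 5% of the preceding interval are treated as
artifacts and skipped, and anchors within `L` intervals of either series
end are dropped rather than zero-padded (padding biases the window average
toward the series mean). With the default `L = 2`, the anchor-aligned
averages `X(k)`, k = −2…1, are contrasted by the Haar-style quantification
`(X(0) + X(1) − X(−1) − X(−2))/4`. DC is positive and AC negative on
physiologic series; a series with no valid anchor yields an explicit
undefined-capacity result distinct from a numeric zero. `L` and the artifact
filter are exposed as parameters.

## SVM risk models

Three prespecified feature vectors are compared: the 5-feature **HRV
complex** (SDNN, SDANN, ASDNN, mean NN, triangular index), **dim6** (HRV
time-domain without mean NN, plus DC and AC) and **dim8** (all eight
post-selection features).

* **Kernel.** RBF by default, with `hyperparameter_search()` providing
  grid selection by inner-LOO accuracy for nested cross-validation; the
  source methodology tuned kernel parameters but named neither kernel nor
  grid.
* **Class weighting.** At 196:12 imbalance an unweighted SVM can reach 94%
  accuracy by predicting "survivor" always; per-fold class weights inversely
  proportional to class frequency make the high-sensitivity operating
  regime reachable. Weighting is the default and can be disabled.
* **Leave-one-out.** Each patient is scored by a model fitted to all other
  patients. Feature standardization and class weights are recomputed inside
  every fold; the held-out row (and label) never touches its own model — a
  leakage test asserts that flipping a patient's label cannot move that
  patient's own score.
* **Score normalization.** Decision values are mapped to [0, 1] by a
  class-balanced conformal-rank calibration: the score is the class-weighted
  fraction of the training fold's decision values lying below the test
  value (half-credit for ties), with the decision boundary `dv = 0`
  included in the reference set at single-observation weight. This keeps
  two properties that a sigmoid (Platt) calibration does not deliver
  simultaneously: (i) a patient on the death side of the hyperplane always
  scores above the prespecified 0.5 cutoff, and (ii) pooling the scores
  across LOO folds yields an unbiased null — with label-permuted data the
  pooled AUC is 0.5 within Monte-Carlo error (asserted over 20 seeded
  permutations in the tests). Pooled cross-validated scores are otherwise
  pessimistically biased: the fold-level shift of the decision function
  anti-correlates with the held-out label, a known artifact of pooling
  LOO scores that sigmoid calibration inherits because its location is
  anchored to the training labels. Rank calibration cancels the fold-level
  shift because only the test value's position *within its own fold's score
  distribution* matters. It is monotone in the decision value
  within each fold; Platt calibration remains available via
  `svm_model_spec(calibration = "platt")`.
* **Cutoff.** Death is predicted iff score > 0.5, strictly; a score of
  exactly 0.5 predicts survival.

## Evaluation layer

Metrics are reported in percent. ROC curves sweep all distinct score values
(ties move operating points simultaneously) and the trapezoidal AUC equals
the Mann–Whitney concordance probability with tie half-credit — asserted
against an O(n²) pair loop in the tests. Correlated ROC curves are compared
with DeLong's test (via pROC); the "nonparametric test" of the source
methodology is not named further, and DeLong is the standard choice for
paired AUCs. Integer confusion matrices are reconstructed from printed
sensitivity/specificity rows by nearest-integer rounding (halves away from
zero) of `sens·n_pos/100` and `spec·n_neg/100`; this reconstruction exactly
regenerates every printed PPV/NPV/accuracy cell of the published tables,
with one exception — the published full-cohort LVEF accuracy (91.83) is
inconsistent with its own row, whose implied matrix (tp 3, fn 9, tn 187,
fp 9) gives 190/208 = 91.35. The package treats 91.35 as the
self-consistent value and flags the discrepancy.

The LVEF > 0.35 subgroup keeps patients strictly above the cutoff. With the
published baseline counts (9 of 196 survivors and 3 of 12 deaths below
0.35) this leaves 187 survivors and 9 deaths, the class sizes behind the
subgroup table.

## The synthetic-cohort module

**Feature level.** Patients are drawn from a truncated multivariate normal
per class: published summaries are mean ± SD, consistent with approximately
normal marginals, and truncation at physical bounds (SDNN > 0, DC > 0,
AC < 0, triangular index ≥ 1, ...) keeps every draw admissible. Only
marginal moments are published, so the between-feature correlation is a
free simulation knob: the default is the identity matrix, making the
assumption explicit and overridable through `cohort_spec(correlation =)`.
LVEF is drawn from the published per-class echocardiographic summaries
rescaled to fractions. Consequences to keep in mind: real HRV features are
strongly mutually correlated, so the default independent cohort carries
*more* joint information than real data — synthetic model AUCs (~0.98) are
optimistic and are never compared against the clinical AUCs, which are
explicitly out of reach without the original recordings.

**Signal level.** Sinus variability is composed of a circadian sinusoid, a
slowly mixing AR(1) (φ = 0.995; drives between-segment, SDANN-type
variance), a respiratory-band oscillation (period ≈ 4 beats) and white
jitter (together the within-segment, ASDNN-type variance). Defaults
(mean NN 900 ms, circadian amplitude 90 ms, long-term SD 60 ms, short-term
SD 25 ms, 5 VPC/h) were chosen once to land in the survivor-like range of
the published moments. VPCs arrive as a Poisson process (≥ 25 beats apart),
replace one sinus beat with a coupling interval of `coupling_fraction` ×
the local interval, and are followed by a fully compensatory pause
(2·local − coupling, the textbook ventricular-ectopy convention) and a
programmed turbulence pattern: beats 1–2 carry the onset offset, beats 2–7
a linear ramp at the programmed slope, beats 8–15 a linear return to
baseline. By construction the extracted TO and TS equal the programmed
values exactly on noiseless profiles, which is what the parameter-recovery
tests assert. The generator does not emulate atrial fibrillation (excluded
from the study population), QRS morphology, or recording gaps; artifact
corruption is available separately via `inject_artifacts()`.

## Numerical conventions and degenerate inputs

* Population SD everywhere; tie at the 0.5 score cutoff → survivor;
  threshold comparators use strict `<` (SDNN < 70 ms, DC < 4.5 ms,
  LVEF < 0.35); subgroup bound strict `>`.
* Empty NN series, zero PRSA anchors and zero VPC episodes produce explicit
  signals (error or `NA`-with-flag), never silent zeros.
* Identical score vectors short-circuit the DeLong comparison to
  p = 1 / Δ = 0 (the variance of the difference is 0 there).
* All generators are deterministic given their seed; the pipeline derives
  per-stage seeds from the single configured seed.

## Problem sizes in the test suite

The test suite exercises moment convergence at n = 10⁴ per class (1%
tolerance), oracle equivalence on 1000 random series, the binormal AUC
check at n = 10⁵, the permutation null with 20 seeds at n = 200, and DeLong
calibration with 500 null replicates — sizes chosen so each property is
measured well inside its Monte-Carlo error while the whole suite runs in a
few minutes.

## Known limitations

* Feature-level cohorts match published marginals only; joint structure is
  assumed, so classifier performance on synthetic cohorts does not estimate
  clinical performance.
* Turbulence formulas and PRSA parameters follow the cited standard
  methodologies, not recording-level reconciliation against the original
  cohort (impossible without its data).
* The LOO sensitivity of the SVM at the 0.5 cutoff on a 12-death cohort is
  volatile: each left-out death removes 1/12 of the minority class, and
  rank-calibrated scores for extreme minority members sit near the cutoff.
  AUC, which the methodology treats as primary, is the stable quantity.
* No frequency-domain HRV, RMSSD or pNN50 (absent from the feature set this
  methodology selected), no QRS detection, and no uniform-grid resampling.
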