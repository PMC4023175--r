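# hrvrisk

Risk stratification of cardiac death after acute myocardial infarction (AMI)
from 24-hour Holter RR-interval recordings. Conventional single HRV indices
(SDNN, deceleration capacity, LVEF) capture one facet of autonomic
dysfunction each and stratify post-AMI risk poorly on their own; `hrvrisk`
implements the integrated alternative: ten heart-rate-dynamics features are
extracted per recording and combined into support-vector-machine risk models
evaluated by leave-one-out cross-validation (LOO-CV), then compared against
the single-index threshold classifiers with ROC/AUC methodology.

## What it computes

**Features** (per 24-h recording, from normal-to-normal (NN) intervals):

- Time domain: SDNN, SDANN (SD of 5-minute segment means), ASDNN (mean of
  5-minute segment SDs), mean NN, HRV triangular index (NN count / modal
  histogram bin, bin width 1000/128 ms), mean heart rate (60000 / mean NN).
- Heart-rate turbulence after ventricular premature complexes (VPCs):
  onset `TO = 100·((RR₁+RR₂) − (RR₋₂+RR₋₁)) / (RR₋₂+RR₋₁)` (%) and slope
  `TS` = the maximum least-squares slope over any 5 consecutive intervals of
  the first 15 post-ectopic sinus beats of the episode-averaged tachogram
  (ms/beat). Recordings without eligible VPCs carry no turbulence value,
  which is why TO/TS never enter the classifiers.
- Phase-rectified signal averaging: deceleration capacity
  `DC = (X(0) + X(1) − X(−1) − X(−2)) / 4` over anchor-aligned averages
  `X(k)` at deceleration anchors (and AC, the acceleration analogue).

**Models**: SVM (RBF kernel, class-weighted for the ~16:1 survivor:death
imbalance) over three prespecified feature vectors — the 5-feature *HRV
complex* (SDNN, SDANN, ASDNN, mean NN, triangular index), a 6-dimension
vector (HRV + DC + AC, mean NN removed) and an 8-dimension vector (all
features). Each patient is scored by a model trained on all others (LOO);
decision values are normalized to [0, 1] by a class-balanced conformal-rank
calibration, and scores > 0.5 predict cardiac death.

**Evaluation**: confusion-matrix metrics (accuracy, sensitivity,
specificity, PPV, NPV), trapezoidal ROC/AUC, DeLong comparison of correlated
ROC curves, reconstruction of integer confusion matrices from published
sensitivity/specificity rows, and the LVEF > 0.35 subgroup analysis.

**Synthetic cohorts**: because the original patient recordings are not
deposited, a simulator provides (i) feature-level cohorts drawn from the
published class-conditional moments (truncated multivariate normal) and
(ii) signal-level 24-h RR tachograms with circadian trend, slow and fast
variability, VPCs with compensatory pauses, and programmed turbulence whose
truth parameters the extractors must recover.

## Worked example

```r
library(hrvrisk)

# one synthetic 24-h recording and its feature record
series <- generate_rr_series(rr_profile(duration = 24, vpc_rate = 5, seed = 7))
feats  <- extract_features(series)
round(unlist(feats[c("sdnn","sdann","asdnn","mean_nn","tri_index",
                     "mean_hr","dc","ac","to","ts")]), 2)
#>      sdnn     sdann     asdnn   mean_nn tri_index   mean_hr        dc        ac
#>     88.51     75.88     43.88    899.39     29.84     66.71      8.66     -8.95
#>        to        ts
#>     -2.49      7.77

# a 196/12 cohort with the published class-conditional moments,
# scored by the HRV-complex SVM under leave-one-out cross-validation
coh <- generate_feature_cohort(cohort_spec(196, 12, seed = 42))
dm  <- assemble_design_matrix(coh, feature_vector_config("hrv_complex"))
sc  <- loo_scores(dm$x, dm$y, patient_id = dm$patient_id)
roc_auc(sc$score, sc$truth)$auc
#> [1] 0.9859694

compare_rocs(sc$score, -coh$sdnn, coh$outcome)$p_value   # SVM vs SDNN alone
#> [1] 0.006065284
```

The feature values are one draw from the survivor-like default profile: SDNN
88.5 ms and DC 8.7 ms are in the normal range, the recovered turbulence
onset (−2.49%) is the profile's programmed early acceleration, and TS is
positively biased away from its programmed 8 ms/beat by within-recording
noise (the maximum over 11 regression windows). On the feature-level cohort
the HRV-complex model ranks nearly all deaths above the survivors (AUC
0.986) and beats the SDNN-only ROC curve at p ≈ 0.006 — the synthetic
cohort's independent features make this an easier problem than the real
cohort, so these AUCs characterize the pipeline, not the clinical study.

Consistency of the published evaluation tables can be re-derived from their
sensitivity/specificity rows alone:

```r
diagnostic_metrics(reconstruct_confusion(91.67, 79.08, 12, 196))
#>   accuracy sensitivity specificity      ppv      npv
#> 1 79.80769    91.66667    79.08163 21.15385 99.35897
```

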