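#' Class-conditional moments of the eight post-selection Holter features
#'
#' Per-class (survivor vs cardiac death) mean and standard deviation of the
#' eight heart-rate-dynamics features retained after feature selection in the
#' original 208-patient post-infarction cohort, together with the physical
#' admissibility bounds used when simulating feature-level cohorts. Units:
#' `sdnn`, `sdann`, `asdnn`, `mean_nn` in ms; `tri_index` unitless;
#' `dc`, `ac` in ms; `mean_hr` in beats/min.
#'
#' @return A data frame with columns `feature`, `mean_survivor`,
#'   `sd_survivor`, `mean_death`, `sd_death`, `lower`, `upper`.
#' @export
#' @examples
#' table_feature_distributions()
table_feature_distributions <- function() {
  data.frame(
    feature       = c("sdnn", "sdann", "asdnn", "mean_nn",
                      "tri_index", "dc", "ac", "mean_hr"),
    mean_survivor = c(96.22, 83.66, 43.40, 893.54, 27.48, 6.31, -6.27, 68.36),
    sd_survivor   = c(27.86, 26.65, 13.67, 115.46, 8.81, 1.91, 1.98, 9.00),
    mean_death    = c(64.52, 58.47, 25.74, 826.85, 16.80, 4.21, -4.12, 73.50),
    sd_death      = c(14.65, 15.68, 6.84, 84.21, 4.20, 1.44, 1.42, 7.70),
    lower         = c(0, 0, 0, 300, 1, 0, -Inf, 20),
    upper         = c(Inf, Inf, Inf, 2000, Inf, Inf, 0, 220),
    stringsAsFactors = FALSE
  )
}

#' Published operating points of the reference cohort classifiers
#'
#' Sensitivity and specificity (percent) reported for each classifier in the
#' original cohort, alongside the published accuracy, positive and negative
#' predictive values, for the full cohort (12 cardiac deaths, 196 survivors)
#' and the LVEF > 0.35 subgroup (9 deaths, 187 survivors). These printed
#' operating points are inputs: [reconstruct_confusion()] inverts each row
#' into an integer confusion matrix and [diagnostic_metrics()] recomputes the
#' derived cells, a consistency check of the whole metric layer.
#'
#' The published full-cohort LVEF accuracy (91.83) is arithmetically
#' inconsistent with its own sensitivity/specificity row, which implies
#' tp = 3, tn = 187 and hence accuracy 190/208 = 91.35; the value stored in
#' `accuracy` for that row is the self-consistent 91.35 and the discrepancy is
#' flagged in `accuracy_note`.
#'
#' @return A data frame with columns `table` (`"full"` or `"lvef_gt_035"`),
#'   `method`, `n_pos`, `n_neg`, `sensitivity`, `specificity`, `accuracy`,
#'   `ppv`, `npv`, `accuracy_note`.
#' @export
published_operating_points <- function() {
  full <- data.frame(
    table       = "full",
    method      = c("hrv_complex", "dim6", "dim8", "lvef", "sdnn", "dc"),
    n_pos       = 12L, n_neg = 196L,
    sensitivity = c(91.67, 91.67, 83.33, 25.00, 58.33, 50.00),
    specificity = c(79.08, 78.57, 79.08, 95.41, 85.20, 82.65),
    accuracy    = c(79.81, 79.33, 79.33, 91.35, 83.65, 80.77),
    ppv         = c(21.15, 20.75, 19.61, 25.00, 19.44, 15.00),
    npv         = c(99.36, 99.35, 98.73, 95.41, 97.09, 96.43),
    accuracy_note = c("", "", "", "published value 91.83 is inconsistent with the row", "", ""),
    stringsAsFactors = FALSE
  )
  sub <- data.frame(
    table       = "lvef_gt_035",
    method      = c("hrv_complex", "sdnn", "dc"),
    n_pos       = 9L, n_neg = 187L,
    sensitivity = c(88.89, 55.56, 55.56),
    specificity = c(80.21, 86.63, 82.89),
    accuracy    = NA_real_,
    ppv         = c(17.78, 16.67, 13.51),
    npv         = c(99.34, 97.59, 97.48),
    accuracy_note = "",
    stringsAsFactors = FALSE
  )
  rbind(full, sub)
}

#' Cohort exclusion arithmetic
#'
#' Applies the enrolment exclusions to the screened cohort: recordings lost to
#' non-cardiac death and recordings with inadequately analyzable data are
#' removed, and the cardiac-death prevalence among the analyzable recordings
#' is computed.
#'
#' @param enrolled Number of patients enrolled.
#' @param non_cardiac_deaths Recordings excluded for non-cardiac death.
#' @param inadequate Recordings excluded as inadequately analyzable.
#' @param cardiac_deaths Cardiac deaths among the analyzable recordings.
#' @return A list with `analyzable`, `survivors`, `cardiac_deaths` and
#'   `prevalence_pct` (percent of analyzable recordings).
#' @export
#' @examples
#' cohort_exclusion_arithmetic()
cohort_exclusion_arithmetic <- function(enrolled = 226L, non_cardiac_deaths = 6L,
                                        inadequate = 12L, cardiac_deaths = 12L) {
  stopifnot(enrolled >= non_cardiac_deaths + inadequate)
  analyzable <- enrolled - non_cardiac_deaths - inadequate
  stopifnot(cardiac_deaths <= analyzable)
  list(
    analyzable     = analyzable,
    survivors      = analyzable - cardiac_deaths,
    cardiac_deaths = cardiac_deaths,
    prevalence_pct = 100 * cardiac_deaths / analyzable
  )
}

#' Conventional abnormality thresholds for the single-index comparators
#'
#' SDNN < 70 ms, deceleration capacity < 4.5 ms and LVEF < 0.35 are the
#' prespecified abnormality cutoffs used by the single-index threshold
#' classifiers; values strictly below the cutoff predict cardiac death.
#'
#' @return Named numeric vector with elements `sdnn`, `dc`, `lvef`.
#' @export
comparator_thresholds <- function() {
  c(sdnn = 70, dc = 4.5, lvef = 0.35)
}
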