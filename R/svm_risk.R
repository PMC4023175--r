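#' Feature-vector model configurations
#'
#' The three prespecified feature combinations: `hrv_complex` is the
#' 5-feature time-domain HRV vector (SDNN, SDANN, ASDNN, mean NN, triangular
#' index); `dim6` adds DC and AC but removes mean NN; `dim8` uses all eight
#' post-selection features. Heart-rate turbulence never enters a model
#' because recordings without ventricular ectopy carry no turbulence value.
#'
#' @param name One of `"hrv_complex"`, `"dim6"`, `"dim8"`.
#' @return Object of class `feature_vector_config`: list with `name` and the
#'   ordered `features` character vector.
#' @export
#' @examples
#' feature_vector_config("dim6")$features
feature_vector_config <- function(name = c("hrv_complex", "dim6", "dim8")) {
  name <- match.arg(name)
  features <- switch(name,
    hrv_complex = c("sdnn", "sdann", "asdnn", "mean_nn", "tri_index"),
    dim6        = c("sdnn", "sdann", "asdnn", "tri_index", "dc", "ac"),
    dim8        = c("sdnn", "sdann", "asdnn", "mean_nn", "tri_index",
                    "dc", "ac", "mean_hr")
  )
  structure(list(name = name, features = features),
            class = "feature_vector_config")
}

#' Assemble a design matrix for one model
#'
#' Pulls the configured feature columns (in the configured order) from a
#' feature table, drops patients with missing values (listed in a warning),
#' and records per-column standardization parameters computed on the
#' retained rows. The standardized matrix is informational; model fitting
#' re-standardizes inside each cross-validation fold to avoid leakage.
#'
#' @param cohort Feature table: data frame with one row per patient,
#'   the feature columns, and `outcome` (factor `survivor`/`death`).
#' @param config A [feature_vector_config()].
#' @return List with `x` (raw matrix), `x_std` (standardized), `center`,
#'   `scale`, `y` (outcome factor), `patient_id`, `excluded` (ids dropped
#'   for missingness).
#' @export
assemble_design_matrix <- function(cohort, config) {
  stopifnot(is.data.frame(cohort), inherits(config, "feature_vector_config"))
  missing_cols <- setdiff(config$features, names(cohort))
  if (length(missing_cols))
    stop("feature table lacks column(s) required by model '", config$name,
         "': ", paste(missing_cols, collapse = ", "))
  if (!"outcome" %in% names(cohort)) stop("feature table lacks an outcome column")
  ids <- if ("patient_id" %in% names(cohort)) as.character(cohort$patient_id)
         else as.character(seq_len(nrow(cohort)))
  x <- as.matrix(cohort[, config$features, drop = FALSE])
  storage.mode(x) <- "double"
  bad <- !stats::complete.cases(x)
  if (any(bad))
    warning("excluding ", sum(bad), " patient(s) with missing feature values: ",
            paste(ids[bad], collapse = ", "))
  x <- x[!bad, , drop = FALSE]
  y <- factor(as.character(cohort$outcome[!bad]),
              levels = c("survivor", "death"))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(x = x, x_std = scale(x, ctr, scl), center = ctr, scale = scl,
       y = y, patient_id = ids[!bad], excluded = ids[bad])
}

#' SVM model specification
#'
#' @param kernel libsvm kernel name (`"radial"`, `"linear"`, ...).
#' @param cost Regularization constant C.
#' @param gamma RBF bandwidth; `NULL` uses the libsvm default `1/p`.
#' @param class_weight `"balanced"` weights each class inversely to its fold
#'   frequency (essential at 196:12 imbalance); `"none"` disables weighting.
#' @param calibration Score normalization onto `[0, 1]`: `"rank"` (default)
#'   is the class-balanced percentile of the test decision value among the
#'   training fold's decision values with the decision boundary included in
#'   the reference set, so a patient on the death side of the hyperplane
#'   always scores above 0.5; `"platt"` is the sigmoid probability fitted by
#'   libsvm's internal cross-validation.
#' @return Object of class `svm_model_spec`.
#' @export
svm_model_spec <- function(kernel = "radial", cost = 1, gamma = NULL,
                           class_weight = c("balanced", "none"),
                           calibration = c("rank", "platt")) {
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 class_weight = match.arg(class_weight),
                 calibration = match.arg(calibration)),
            class = "svm_model_spec")
}

# Fit a (possibly class-weighted) SVM on one training fold.
fit_fold <- function(x_tr, y_tr, spec, probability = FALSE, seed = NULL) {
  args <- list(x = x_tr, y = y_tr, kernel = spec$kernel, cost = spec$cost,
               probability = probability)
  if (!is.null(spec$gamma)) args$gamma <- spec$gamma
  if (spec$class_weight == "balanced") {
    tab <- table(y_tr)
    cw <- as.numeric(sum(tab) / (2 * tab))
    names(cw) <- names(tab)
    args$class.weights <- cw
  }
  if (!is.null(seed)) set.seed(seed)
  do.call(e1071::svm, args)
}

# Decision values oriented so that larger = death. libsvm reports the
# decision value for the class pair named in the column label "A/B",
# positive meaning class A.
decision_values <- function(fit, x) {
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  sgn <- if (startsWith(colnames(dv)[1], "death/")) 1 else -1
  sgn * dv[, 1]
}

# Class-balanced conformal-rank calibration: the score is the weighted
# fraction of the training fold's decision values lying below the test
# value (half-weight for ties), with each class carrying total weight 1/2
# and the decision boundary dv = 0 included at single-observation weight so
# sign(dv) alone decides the 0.5 side. Monotone in the decision value.
rank_calibrate <- function(dv_train, y_train, dv_test) {
  wt <- ifelse(y_train == "death",
               0.5 / sum(y_train == "death"),
               0.5 / sum(y_train == "survivor"))
  d <- 1 / length(dv_train)
  vapply(dv_test, function(v) {
    (sum(wt[dv_train < v]) + 0.5 * sum(wt[dv_train == v]) +
       d * (v > 0) + 0.5 * d * (v == 0)) / (1 + d)
  }, numeric(1))
}

#' Leave-one-out cross-validated risk scores
#'
#' For each patient, an SVM is fitted on all other patients (feature
#' standardization and class weights recomputed inside the fold; the test
#' row never influences its own model) and the patient's decision value is
#' mapped onto `[0, 1]` by the configured calibration. Scores above the
#' prespecified 0.5 cutoff predict cardiac death.
#'
#' @param x Raw (unstandardized) feature matrix, one row per patient.
#' @param y Outcome factor with levels `survivor`, `death` (at least two
#'   patients per class).
#' @param spec An [svm_model_spec()].
#' @param patient_id Optional patient identifiers.
#' @param seed Integer seed (only consulted by the `"platt"` calibration,
#'   whose internal cross-validation is randomized; `"rank"` scoring is
#'   fully deterministic).
#' @return Data frame of class `risk_scores` with columns `patient_id`,
#'   `score`, `predicted`, `truth`.
#' @export
loo_scores <- function(x, y, spec = svm_model_spec(),
                       patient_id = NULL, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("survivor", "death"))
  if (nrow(x) != length(y)) stop("x and y disagree in length")
  tab <- table(y)
  if (any(tab < 2))
    stop("leave-one-out requires at least 2 patients per class; class '",
         names(tab)[which.min(tab)], "' has ", min(tab))
  if (is.null(patient_id)) patient_id <- as.character(seq_len(nrow(x)))
  n <- nrow(x)
  score <- numeric(n)
  for (i in seq_len(n)) {
    y_tr <- y[-i]
    if (any(table(y_tr) == 0))
      stop("fold ", i, " lost all members of class '",
           names(which(table(y_tr) == 0))[1], "'")
    # standardize inside the fold
    ctr <- colMeans(x[-i, , drop = FALSE])
    scl <- apply(x[-i, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    x_tr <- scale(x[-i, , drop = FALSE], ctr, scl)
    x_te <- scale(x[i, , drop = FALSE], ctr, scl)
    if (spec$calibration == "platt") {
      fit <- fit_fold(x_tr, y_tr, spec, probability = TRUE,
                      seed = seed * 1000L + i)
      pr <- predict(fit, x_te, probability = TRUE)
      score[i] <- attr(pr, "probabilities")[1, "death"]
    } else {
      fit <- fit_fold(x_tr, y_tr, spec)
      dv_tr <- decision_values(fit, x_tr)
      score[i] <- rank_calibrate(dv_tr, y_tr, decision_values(fit, x_te))
    }
  }
  structure(data.frame(patient_id = patient_id, score = score,
                       predicted = classify_scores(score), truth = y,
                       stringsAsFactors = FALSE),
            class = c("risk_scores", "data.frame"))
}

#' Dichotomize risk scores at the prespecified 0.5 cutoff
#'
#' Scores strictly above 0.5 predict cardiac death; 0.5 itself (and below)
#' predicts survival, since death is defined strictly as score > 0.5.
#'
#' @param scores Numeric scores in `[0, 1]`, or a `risk_scores` data frame.
#' @return Factor with levels `survivor`, `death`.
#' @export
classify_scores <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$score
  factor(ifelse(scores > 0.5, "death", "survivor"),
         levels = c("survivor", "death"))
}

#' Grid search for SVM hyper-parameters
#'
#' Evaluates every row of the grid by inner leave-one-out classification
#' accuracy on the supplied data and returns the specification with the best
#' accuracy (first row wins ties, so the result is deterministic). Intended
#' as the inner loop of a nested cross-validation: call it on training folds
#' only, leaving the outer evaluation untouched.
#'
#' @param x Raw feature matrix.
#' @param y Outcome factor.
#' @param grid Data frame of candidate settings with columns `cost` and
#'   `gamma` (`NA` gamma = libsvm default).
#' @param spec Base [svm_model_spec()] supplying kernel, weighting and
#'   calibration.
#' @param seed Passed to [loo_scores()].
#' @return List with `spec` (best [svm_model_spec()]), `accuracy` (per grid
#'   row), `best` (row index).
#' @export
hyperparameter_search <- function(x, y, grid, spec = svm_model_spec(),
                                  seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1,
            all(c("cost", "gamma") %in% names(grid)))
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    sp <- spec
    sp$cost <- grid$cost[g]
    sp$gamma <- if (is.na(grid$gamma[g])) NULL else grid$gamma[g]
    sc <- loo_scores(x, y, sp, seed = seed)
    mean(sc$predicted == sc$truth)
  }, numeric(1))
  best <- which.max(acc)
  out <- spec
  out$cost <- grid$cost[best]
  out$gamma <- if (is.na(grid$gamma[best])) NULL else grid$gamma[best]
  list(spec = out, accuracy = acc, best = best)
}
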