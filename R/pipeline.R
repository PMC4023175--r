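#' Extract the full feature record of one recording
#'
#' Runs a recording through the whole feature stack: sinus-coverage gate,
#' NN extraction, 5-minute segmentation, time-domain HRV, heart-rate
#' turbulence and PRSA capacities.
#'
#' @param series An [rr_series()].
#' @param sinus_min_fraction Gate threshold (recording rejected below it).
#' @param prsa_L,prsa_anchor_filter PRSA parameters.
#' @return One-row data frame with the feature-table columns (`sdnn`,
#'   `sdann`, `asdnn`, `mean_nn`, `tri_index`, `mean_hr`, `dc`, `ac`, `to`,
#'   `ts`, `hrt_available`, `sinus_fraction`).
#' @export
extract_features <- function(series, sinus_min_fraction = 0.80,
                             prsa_L = 2, prsa_anchor_filter = 0.05) {
  gate <- sinus_fraction_gate(series, sinus_min_fraction)
  if (!gate$pass)
    stop(sprintf("recording rejected: sinus rhythm covers %.1f%% of the recording (< %.0f%%)",
                 100 * gate$fraction, 100 * sinus_min_fraction))
  nn <- segment_5min(extract_nn(series))
  td <- hrv_time_features(nn)
  pr <- prsa_features(nn, L = prsa_L, anchor_filter = prsa_anchor_filter)
  ht <- hrt_features(series)
  cbind(td, data.frame(dc = pr$dc, ac = pr$ac, to = ht$to, ts = ht$ts,
                       hrt_available = ht$available,
                       sinus_fraction = gate$fraction))
}

#' Validate a pipeline run configuration
#'
#' Fills defaults and checks a configuration list (or YAML file). A seed is
#' mandatory: every stochastic stage draws from it through fixed per-stage
#' offsets, so a configuration fully determines a run.
#'
#' @param config Named list, or path to a YAML file.
#' @return Validated configuration list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    seed = NULL,
    n_survivors = 196L, n_deaths = 12L,
    n_signal_patients = 0L,                 # signal-level tachograms to simulate
    signal_duration = 24,                   # hours
    artifact_fraction = 0,                  # beats corrupted per signal series
    sinus_min_fraction = 0.80,
    prsa_L = 2, prsa_anchor_filter = 0.05,
    models = c("hrv_complex", "dim6", "dim8"),
    svm_cost = 1, svm_gamma = NA,
    out_dir = NULL
  )
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  stopifnot(cfg$n_survivors >= 0, cfg$n_deaths >= 2,
            cfg$sinus_min_fraction >= 0, cfg$sinus_min_fraction <= 1,
            all(cfg$models %in% c("hrv_complex", "dim6", "dim8")))
  structure(cfg, class = c("run_config", "list"))
}

#' Run the simulate -> extract -> train/eval -> report pipeline
#'
#' Generates a feature-level synthetic cohort (and, optionally, signal-level
#' tachograms whose extracted features are written alongside), evaluates the
#' configured SVM models by leave-one-out cross-validation and the three
#' single-index comparators, and writes all artifacts plus a machine-readable
#' manifest into the output directory. Re-running the same configuration
#' reproduces bit-identical tables.
#'
#' @param config A [run_config()] (or list / YAML path accepted by it).
#' @return Invisibly, a list with the feature table, per-model `risk_scores`,
#'   the evaluation table and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # --- simulate (feature level) -------------------------------------------
  cohort <- generate_feature_cohort(
    cohort_spec(cfg$n_survivors, cfg$n_deaths, seed = cfg$seed))
  # --- simulate (signal level, optional) + extract ------------------------
  exclusions <- data.frame(patient_id = character(0), reason = character(0))
  if (cfg$n_signal_patients > 0) {
    rows <- list()
    for (k in seq_len(cfg$n_signal_patients)) {
      prof <- rr_profile(duration = cfg$signal_duration,
                         seed = cfg$seed + 1000L + k)
      series <- generate_rr_series(prof)
      if (cfg$artifact_fraction > 0)
        series <- inject_artifacts(series, cfg$artifact_fraction,
                                   seed = cfg$seed + 2000L + k)
      p <- file.path(cfg$out_dir, sprintf("rr_%03d.csv", k))
      write_rr_file(series, p)
      paths[[sprintf("rr_%03d", k)]] <- p
      feats <- tryCatch(
        extract_features(series, cfg$sinus_min_fraction,
                         cfg$prsa_L, cfg$prsa_anchor_filter),
        error = function(e) e)
      if (inherits(feats, "error")) {
        exclusions <- rbind(exclusions, data.frame(
          patient_id = sprintf("S%03d", k), reason = conditionMessage(feats)))
      } else {
        rows[[length(rows) + 1]] <- cbind(
          patient_id = sprintf("S%03d", k), feats)
      }
    }
    if (length(rows)) {
      sig <- do.call(rbind, rows)
      paths$signal_features <- file.path(cfg$out_dir, "signal_features.csv")
      write.csv(sig, paths$signal_features, row.names = FALSE)
    }
    paths$exclusions <- file.path(cfg$out_dir, "exclusions.csv")
    write.csv(exclusions, paths$exclusions, row.names = FALSE)
  }

  paths$feature_table <- file.path(cfg$out_dir, "feature_table.csv")
  write.csv(cohort, paths$feature_table, row.names = FALSE)

  # --- train / evaluate ----------------------------------------------------
  spec <- svm_model_spec(cost = cfg$svm_cost,
                         gamma = if (is.na(cfg$svm_gamma)) NULL else cfg$svm_gamma)
  scores <- list()
  eval_rows <- list()
  for (m in cfg$models) {
    dm <- assemble_design_matrix(cohort, feature_vector_config(m))
    sc <- loo_scores(dm$x, dm$y, spec, patient_id = dm$patient_id,
                     seed = cfg$seed)
    scores[[m]] <- sc
    p <- file.path(cfg$out_dir, paste0("scores_", m, ".csv"))
    write.csv(sc, p, row.names = FALSE)
    paths[[paste0("scores_", m)]] <- p
    met <- diagnostic_metrics(confusion_from_predictions(sc$truth, sc$predicted))
    roc <- roc_auc(sc$score, sc$truth)
    eval_rows[[m]] <- cbind(method = m, met, auc = roc$auc)
    p <- file.path(cfg$out_dir, paste0("roc_", m, ".csv"))
    write.csv(roc$points, p, row.names = FALSE)
    paths[[paste0("roc_", m)]] <- p
  }
  # single-index comparators (higher value = lower risk, so ROC uses -value)
  thr <- comparator_thresholds()
  for (cmp in c("sdnn", "dc", "lvef")) {
    pred <- threshold_classifier(cohort[[cmp]], thr[[cmp]])
    met <- diagnostic_metrics(confusion_from_predictions(cohort$outcome, pred))
    roc <- roc_auc(-cohort[[cmp]], cohort$outcome)
    eval_rows[[cmp]] <- cbind(method = cmp, met, auc = roc$auc)
  }
  eval_tab <- do.call(rbind, eval_rows)
  rownames(eval_tab) <- NULL
  paths$evaluation <- file.path(cfg$out_dir, "evaluation.csv")
  write.csv(eval_tab, paths$evaluation, row.names = FALSE)

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("hrvrisk")),
    artifacts = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, scores = scores, evaluation = eval_tab,
                 exclusions = exclusions, manifest = manifest,
                 paths = paths))
}

#' Validate a feature-table CSV
#'
#' Checks the feature-table dialect: required columns present, numeric
#' types, physically admissible ranges (positive SDNN/SDANN/ASDNN and mean
#' NN, triangular index >= 1, positive DC, negative AC, LVEF in (0, 1),
#' outcome in `survivor`/`death`). Every violation is reported with its
#' 1-based data row.
#'
#' @param path Path to a feature-table CSV.
#' @return Data frame of violations (`row`, `column`, `problem`); zero rows
#'   for a conforming table.
#' @export
validate_feature_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "sdnn", "sdann", "asdnn", "mean_nn", "tri_index",
           "dc", "ac", "mean_hr", "lvef", "outcome")
  viol <- data.frame(row = integer(0), column = character(0),
                     problem = character(0))
  note <- function(rows, col, problem) {
    if (length(rows))
      viol <<- rbind(viol, data.frame(row = rows, column = col,
                                      problem = problem))
  }
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    note(0L, missing_cols, "required column absent")
    return(viol)
  }
  pos_cols <- c("sdnn", "sdann", "asdnn", "mean_nn", "mean_hr")
  for (cl in pos_cols)
    note(which(!is.finite(d[[cl]]) | d[[cl]] <= 0), cl, "must be positive")
  note(which(!is.finite(d$tri_index) | d$tri_index < 1), "tri_index",
       "must be >= 1")
  note(which(!is.finite(d$dc) | d$dc <= 0), "dc", "must be positive")
  note(which(!is.finite(d$ac) | d$ac >= 0), "ac", "must be negative")
  note(which(!is.finite(d$lvef) | d$lvef <= 0 | d$lvef >= 1), "lvef",
       "must be in (0, 1)")
  note(which(!d$outcome %in% c("survivor", "death")), "outcome",
       "must be 'survivor' or 'death'")
  viol[order(viol$row), , drop = FALSE]
}
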