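#' Run the full screening study on a cohort
#'
#' End-to-end driver: extract the canonical feature matrix, train and
#' cross-validate the ADRD detector and MMSE severity regressor on the
#' train split, evaluate both on the held-out test split with B bootstrap
#' refits, search traffic-light thresholds on the out-of-fold validation
#' scores, compute selective (Amber-excluded) test metrics, the
#' probability-severity profile, tree attributions, subgroup performance
#' and parity gaps. Everything is deterministic given `seed`.
#'
#' @param cohort List with `transcripts` and `metadata` (from
#'   [generate_cohort()] or [read_cohort()]); metadata must carry
#'   `diagnosis`, `mmse` and a train/test `split`.
#' @param seed Integer seed driving model fits, folds and bootstrap.
#' @param dictionary Category dictionary (default: bundled stand-in).
#' @param k Cross-validation folds (default 10).
#' @param B Bootstrap repeats (default 10).
#' @param grid_resolution Threshold-search grid step (default 0.05).
#' @return A `screening_study` list; see the elements returned below.
#' @export
run_screening_study <- function(cohort, seed = 1L,
                                dictionary = load_dictionary(standin_dictionary_path()),
                                k = 10L, B = 10L,
                                grid_resolution = 0.05) {
  meta <- cohort$metadata
  stopifnot(all(c("diagnosis", "split", "mmse") %in% names(meta)))
  features <- extract_cohort_features(cohort$transcripts, dictionary)
  stopifnot(identical(features$participant_id, meta$participant_id))
  x <- feature_matrix(features)
  y <- meta$diagnosis == "ADRD"
  tr <- meta$split == "train"
  te <- meta$split == "test"
  if (!any(tr) || !any(te))
    stop("cohort metadata must contain both train and test splits")

  ## -- detection -----------------------------------------------------------
  det_spec <- model_spec("detect", seed = seed)
  det_cv <- cross_validate(x[tr, , drop = FALSE], y[tr], det_spec, k = k)
  det_model <- fit_screening_model(x[tr, , drop = FALSE], y[tr], det_spec)
  test_scores <- predict_screening(det_model, x[te, , drop = FALSE])
  det_boot <- bootstrap_test_evaluation(x[tr, , drop = FALSE], y[tr],
                                        x[te, , drop = FALSE], y[te],
                                        det_spec, B = B)
  det_test <- classification_metrics(y[te], test_scores > 0.5, test_scores)
  calibration <- calibration_curve(det_cv$oof_scores, y[tr])

  ## -- traffic-light triage ------------------------------------------------
  search <- grid_search_thresholds(det_cv$oof_scores, y[tr],
                                   resolution = grid_resolution)
  selective <- selective_metrics(test_scores, y[te], search$thresholds)
  full_cov <- classification_metrics(y[te], test_scores > 0.5, test_scores)
  full_j <- youden_j(full_cov$sensitivity / 100, full_cov$specificity / 100)

  ## -- severity regression -------------------------------------------------
  sev_spec <- model_spec("severity", seed = seed)
  sev_cv <- cross_validate(x[tr, , drop = FALSE], meta$mmse[tr], sev_spec,
                           k = k)
  sev_model <- fit_screening_model(x[tr, , drop = FALSE], meta$mmse[tr],
                                   sev_spec)
  mmse_pred <- predict_screening(sev_model, x[te, , drop = FALSE])
  sev_boot <- bootstrap_test_evaluation(x[tr, , drop = FALSE], meta$mmse[tr],
                                        x[te, , drop = FALSE], meta$mmse[te],
                                        sev_spec, B = B)
  sev_test <- regression_metrics(meta$mmse[te], mmse_pred)
  baseline <- regression_metrics(meta$mmse[te],
                                 rep(mean(meta$mmse[tr]), sum(te)))

  ## -- reporting -----------------------------------------------------------
  profile <- probability_severity_profile(test_scores, meta$mmse[te])
  attributions <- feature_attributions(det_model, x[te, , drop = FALSE])
  by_sex <- subgroup_performance(y[te], test_scores, meta$sex[te])
  by_age <- subgroup_performance(y[te], test_scores, age_band(meta$age[te]))
  parity_sex <- demographic_parity_gap(test_scores > 0.5, meta$sex[te])
  odds_sex <- equalized_odds_gaps(y[te], test_scores, meta$sex[te])

  manifest <- list(
    seed = seed, k = k, B = B, grid_resolution = grid_resolution,
    n_train = sum(tr), n_test = sum(te),
    detect_spec = unclass(det_spec), severity_spec = unclass(sev_spec),
    r_version = as.character(getRversion()),
    ranger_version = as.character(utils::packageVersion("ranger")),
    package_version = as.character(utils::packageVersion("speechscreen")))

  structure(list(
    features = features,
    labels = y, train = tr, test = te, metadata = meta,
    detect = list(spec = det_spec, cv = det_cv, model = det_model,
                  test_scores = test_scores, bootstrap = det_boot,
                  test_metrics = det_test, calibration = calibration),
    triage = list(search = search, thresholds = search$thresholds,
                  selective = selective, full_coverage = full_cov,
                  full_youden_j = full_j),
    severity = list(spec = sev_spec, cv = sev_cv, model = sev_model,
                    predictions = mmse_pred, bootstrap = sev_boot,
                    test_metrics = sev_test, baseline = baseline),
    report = list(profile = profile, attributions = attributions,
                  by_sex = by_sex, by_age = by_age,
                  parity_sex = parity_sex, odds_sex = odds_sex),
    manifest = manifest), class = "screening_study")
}

#' @export
print.screening_study <- function(x, ...) {
  cat("<screening study>\n")
  cat(sprintf("  n train/test: %d/%d\n", sum(x$train), sum(x$test)))
  cat(sprintf("  detect  test: AUC %.1f%%, sens %.1f%%, spec %.1f%%, acc %.1f%%\n",
              x$detect$test_metrics$roc_auc, x$detect$test_metrics$sensitivity,
              x$detect$test_metrics$specificity, x$detect$test_metrics$accuracy))
  cat(sprintf("  severity test: MAE %.2f, RMSE %.2f (baseline MAE %.2f)\n",
              x$severity$test_metrics$mae, x$severity$test_metrics$rmse,
              x$severity$baseline$mae))
  cat(sprintf("  triage: Green [0, %.2f], Amber (%.2f, %.2f], Red (%.2f, 1]; coverage %.2f\n",
              x$triage$thresholds$t_low, x$triage$thresholds$t_low,
              x$triage$thresholds$t_high, x$triage$thresholds$t_high,
              x$triage$selective$coverage))
  invisible(x)
}

#' Write the study's main tables and manifest to a directory
#'
#' Emits metrics JSON, the threshold search trace, per-participant zones,
#' the attribution matrix, subgroup tables and the run manifest as
#' plain-text CSV/JSON files.
#'
#' @param study A `screening_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study_reports <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit_json <- function(obj, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    files <<- c(files, p)
  }
  emit_csv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  dm <- study$detect$test_metrics
  sm <- study$severity$test_metrics
  emit_json(list(
    detect = dm[c("sensitivity", "specificity", "roc_auc", "accuracy")],
    detect_bootstrap = study$detect$bootstrap$summary,
    severity = sm, severity_bootstrap = study$severity$bootstrap$summary,
    selective = c(study$triage$selective$metrics[
      c("sensitivity", "specificity", "roc_auc", "accuracy")],
      coverage = study$triage$selective$coverage,
      youden_j = study$triage$selective$youden_j),
    parity = list(sex_gap = study$report$parity_sex,
                  odds = study$report$odds_sex)), "metrics.json")
  emit_json(study$manifest, "manifest.json")
  emit_csv(study$detect$cv$fold_metrics, "cv_detect_folds.csv")
  emit_csv(study$severity$cv$fold_metrics, "cv_severity_folds.csv")
  emit_csv(study$triage$search$trace, "threshold_search_trace.csv")
  emit_csv(data.frame(participant_id = study$metadata$participant_id[study$test],
                      score = study$detect$test_scores,
                      zone = study$triage$selective$zones,
                      mmse = study$metadata$mmse[study$test],
                      mmse_group = mmse_to_group(study$metadata$mmse[study$test])),
           "risk_zones.csv")
  emit_csv(data.frame(participant_id = study$metadata$participant_id[study$test],
                      mmse = study$metadata$mmse[study$test],
                      mmse_group = mmse_to_group(study$metadata$mmse[study$test]),
                      predicted_mmse = study$severity$predictions),
           "severity_predictions.csv")
  emit_csv(study$report$profile$profile, "probability_severity_profile.csv")
  emit_csv(study$report$attributions$ranking, "attribution_ranking.csv")
  emit_csv(cbind(participant_id = study$metadata$participant_id[study$test],
                 as.data.frame(study$report$attributions$contributions)),
           "attribution_matrix.csv")
  emit_csv(rbind(cbind(variable = "sex", study$report$by_sex),
                 cbind(variable = "age_band", study$report$by_age)),
           "subgroup_performance.csv")
  emit_csv(study$detect$calibration, "calibration_curve.csv")
  emit_csv(data.frame(participant_id = study$metadata$participant_id[study$train],
                      oof_score = study$detect$cv$oof_scores),
           "oof_scores.csv")
  invisible(files)
}
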