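# Orchestration of the three validation analyses over long-format feature
# tables: agreement between two measurement systems, test-retest reliability
# across visits, criterion validity against the clinician score, and
# discriminative validity between medication states.

#' Agreement between two feature tables
#'
#' For every feature present in both tables, observations are paired by
#' (subject, visit) and agreement is summarised by ICC(2,1) with confidence
#' bounds and category, plus the Bland-Altman mean difference and 95% limits
#' of agreement.
#'
#' @param features_x,features_y Long-format feature records from the two
#'   systems (e.g. single-device output vs a multi-device reference).
#' @param features Features to compare; all shared names by default.
#' @param conf_level Confidence level for the ICC bounds.
#' @return Tidy tibble, one row per feature.
#' @export
run_agreement <- function(features_x, features_y, features = NULL,
                          conf_level = 0.95) {
  fx <- validate_feature_records(features_x)
  fy <- validate_feature_records(features_y)
  features <- features %||% intersect(unique(fx$feature_name),
                                      unique(fy$feature_name))
  if (!length(features)) abort("no shared features to compare")
  purrr::map_dfr(features, function(f) {
    pair <- dplyr::inner_join(
      dplyr::filter(fx, .data$feature_name == f),
      dplyr::filter(fy, .data$feature_name == f),
      by = c("subject_id", "visit"), suffix = c("_x", "_y")
    )
    res <- icc_or_na(pair[c("value_x", "value_y")], f, conf_level)
    ba <- bland_altman(pair$value_x, pair$value_y)
    tibble::tibble(feature_name = f, n = nrow(pair), icc = res$icc,
                   ci_low = res$ci_low, ci_high = res$ci_high,
                   category = res$category, mean_diff = ba$mean_diff,
                   loa_low = ba$loa_low, loa_high = ba$loa_high)
  })
}

# Batch-safe ICC: a feature that is degenerate across the cohort (e.g. zero
# variance) yields NA bounds with a warning instead of aborting the batch.
icc_or_na <- function(table, feature, conf_level) {
  tryCatch(icc_2_1(table, conf_level = conf_level), error = function(e) {
    warn(sprintf("ICC unavailable for feature `%s`: %s", feature,
                 conditionMessage(e)))
    list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
         category = NA_character_, n = nrow(table))
  })
}

#' Test-retest reliability across two visits
#'
#' ICC(2,1) of each feature between the two visits of the same measurement
#' system (computed on unscored/healthy participants in the study design).
#'
#' @param features Long-format feature records covering both visits.
#' @param visits Length-2 vector of visit identifiers.
#' @param conf_level Confidence level for the ICC bounds.
#' @return Tidy tibble, one row per feature.
#' @export
run_reliability <- function(features, visits = c(1, 2), conf_level = 0.95) {
  fx <- validate_feature_records(features)
  fx <- dplyr::filter(fx, .data$visit %in% visits)
  purrr::map_dfr(unique(fx$feature_name), function(f) {
    wide <- tidyr::pivot_wider(
      dplyr::filter(fx, .data$feature_name == f)[
        c("subject_id", "visit", "value")],
      names_from = "visit", values_from = "value")
    wide <- wide[stats::complete.cases(wide), ]
    res <- icc_or_na(wide[, -1], f, conf_level)
    tibble::tibble(feature_name = f, n = nrow(wide), icc = res$icc,
                   ci_low = res$ci_low, ci_high = res$ci_high,
                   category = res$category)
  })
}

#' Criterion validity: model the clinician gait score from features
#'
#' The full modelling chain on scored participants: pivot the feature records
#' wide, join the metadata, drop highly correlated features, standardize,
#' fit the longitudinal mixed model, select fixed effects by stepwise AIC,
#' compute Type-III Wald tests, and evaluate by leave-one-subject-out
#' cross-validation (RMSE and marginal R-squared).
#'
#' @param features Long-format feature records.
#' @param meta Subject metadata (see [read_subject_metadata()]), including
#'   the clinician score; only scored rows enter the model.
#' @param device_config Which device configuration's records to model.
#' @param prune_threshold Absolute-correlation threshold for feature pruning.
#' @param covariates Covariate columns offered to the model.
#' @return A `gait_criterion` object: list with the fitted/selected model,
#'   the pruning log, Type-III table, and the `gait_model_eval`.
#' @export
run_criterion <- function(features, meta, device_config = "one",
                          prune_threshold = 0.9,
                          covariates = c("age", "gender", "visit", "bmi",
                                         "years_since_first_symptoms")) {
  fx <- validate_feature_records(features)
  fx <- dplyr::filter(fx, .data$device_config == !!device_config)
  if (!nrow(fx)) abort("no records for the requested device_config")
  wide <- tidyr::pivot_wider(fx, id_cols = c("subject_id", "visit"),
                             names_from = "feature_name",
                             values_from = "value")
  feat_names <- setdiff(names(wide), c("subject_id", "visit"))
  data <- dplyr::inner_join(wide, meta, by = c("subject_id", "visit"))
  data <- dplyr::filter(data, !is.na(.data$updrs_gait))
  if (!nrow(data)) abort("no scored observations to model")

  pruned <- prune_correlated(data, cols = feat_names,
                             threshold = prune_threshold)
  data <- standardize_features(data, cols = pruned$retained)
  full <- fit_longitudinal_model(data, features = pruned$retained,
                                 covariates = covariates)
  sel <- stepwise_aic_select(full)
  eval <- loso_predict(sel)
  structure(list(model = sel, full_model = full, pruning = pruned,
                 type3 = type3_tests(sel), eval = eval,
                 device_config = device_config),
            class = "gait_criterion")
}

#' Discriminative validity: predicted score in On vs Off state
#'
#' Pairs each subject's held-out predicted scores by medication state
#' (medians within state if several observations share a state) and applies
#' the paired Wilcoxon signed-rank test.
#'
#' @param eval A `gait_model_eval` whose predictions carry `med_state`, or a
#'   tibble with columns `subject_id`, `med_state`, `predicted`.
#' @param alternative Test sidedness (default two-sided).
#' @return Tibble as returned by [paired_wilcoxon()], with a `n_subjects`
#'   column.
#' @export
run_discrimination <- function(eval, alternative = "two.sided") {
  preds <- if (inherits(eval, "gait_model_eval")) eval$predictions else eval
  need <- c("subject_id", "med_state", "predicted")
  if (!all(need %in% names(preds))) {
    abort("predictions must carry subject_id, med_state, predicted")
  }
  by_state <- preds |>
    dplyr::filter(.data$med_state %in% c("On", "Off")) |>
    dplyr::group_by(.data$subject_id, .data$med_state) |>
    dplyr::summarise(predicted = median(.data$predicted), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "med_state", values_from = "predicted")
  by_state <- by_state[stats::complete.cases(by_state), ]
  if (nrow(by_state) < 2) abort("need at least 2 subjects with both states")
  out <- paired_wilcoxon(by_state$Off, by_state$On,
                         alternative = alternative)
  out$n_subjects <- nrow(by_state)
  out
}

#' @export
print.gait_criterion <- function(x, ...) {
  cat(sprintf("<gait_criterion> %s-device model: RMSE = %.3f, marginal R2 = %.3f\n",
              x$device_config, x$eval$rmse, x$eval$marginal_r2))
  cat("Selected terms:", paste(x$model$selected_terms, collapse = ", "), "\n")
  invisible(x)
}
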