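# End-to-end driver: from a paired training/validation cohort to the final
# filtered subtypes. Each stage is an exported function of its own; this
# wrapper wires them in the study's order and keeps every intermediate
# report.

#' Run the full subtyping pipeline on a training/validation cohort pair
#'
#' Labels both cohorts by onset age, selects model features on the training
#' cohort, splits train/test, imputes with training-fitted normative values,
#' oversamples the minority onset class, grid-searches tree hyperparameters
#' by k-fold cross-validation over unique patients (single-cell grids skip
#' the search), fits the final tree on the oversampled training split,
#' extracts one candidate subtype rule per leaf, and filters the candidates
#' against the validation cohort (imputed with its own normative values).
#'
#' @param training,validation `pd_cohort` objects sharing a schema
#' @param grid a [cv_grid()]
#' @param config a [preprocess_config()]
#' @param min_unique Criteria-1 unique-patient threshold (default 10)
#' @param fraction Criteria-2 match fraction (default 0.05)
#' @param oversample_before_cv reproduce the literal oversample-then-CV
#'   ordering (duplicates may enter validation folds); default `FALSE`
#' @return list with the fitted `tree`, `best` hyperparameters, `cv_table`,
#'   `rules`, `filter` (report + survivors), `test_metrics`, per-stage
#'   `reports`, and the prepared tables (`train`, `test`, `external`)
#' @export
run_subtyping_pipeline <- function(training, validation,
                                   grid = cv_grid(),
                                   config = preprocess_config(),
                                   min_unique = 10L, fraction = 0.05,
                                   oversample_before_cv = FALSE) {
  lab_t <- assign_onset_labels(training)
  sel <- select_features(lab_t$cohort, config)
  features <- attr(sel$cohort, "model_features")

  sp <- split_train_test(sel$cohort$data, config)
  kinds <- stats::setNames(
    ifelse(training$dictionary$kind %in% c("numeric", "integer0_15"),
           "numeric", "categorical"),
    training$dictionary$feature
  )
  imp <- impute_missing(sp$train, sp$test, kinds = kinds,
                        features = features)
  train <- imp$tables[[1]]
  test <- imp$tables[[2]]

  if (oversample_before_cv) {
    train_cv <- random_oversample(train, seed = config$seed)
    cv <- cross_validate_grid(train_cv, grid, features = features,
                              oversample = "before")
    train_fit <- train_cv
  } else {
    cv <- cross_validate_grid(train, grid, features = features,
                              oversample = "within_folds")
    train_fit <- random_oversample(train, seed = config$seed)
  }

  tree <- fit_tree(train_fit[, features, drop = FALSE], train_fit$label,
                   max_depth = cv$best$max_depth,
                   min_samples_leaf = cv$best$min_samples_leaf,
                   ids = train_fit$patient_id)
  rules <- extract_candidate_subtypes(tree, train_fit)

  # external cohort: label in place (excluded stay as NA), impute with its
  # own normative values
  ext <- impute_cohort(validation)
  ext_data <- ext$data
  ext_data$label <- onset_label(ext_data$ageonset)
  filter <- run_filter_pipeline(rules, ext_data, min_unique = min_unique,
                                fraction = fraction)

  list(
    tree = tree, best = cv$best, cv_table = cv$table,
    rules = rules, filter = filter,
    test_metrics = evaluate_tree(tree, test),
    reports = list(labels = lab_t$report, selection = sel$report,
                   split = sp$report,
                   normative_values = imp$normative_values),
    train = train_fit, test = test, external = ext_data,
    features = features
  )
}
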