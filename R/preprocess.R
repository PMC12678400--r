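# Cohort preparation: onset labels, feature selection, normative-value
# imputation, train/test split, and random oversampling of the minority
# onset class. Every fitted quantity (normative values, collinearity
# decisions) depends on training rows only.

#' Preprocessing configuration
#'
#' @param missing_threshold drop features whose missing fraction exceeds
#'   this (default 0.15)
#' @param onset_blocklist features derived from the age of onset, removed
#'   because the class label is computed from it
#' @param collinearity_threshold absolute Pearson correlation at or above
#'   which the later column of a pair is dropped (default 0.999)
#' @param test_fraction held-out fraction for the train/test split
#' @param seed integer seed for the split shuffle
#' @return a `preprocess_config` list
#' @export
preprocess_config <- function(missing_threshold = 0.15,
                              onset_blocklist = c("ageonset",
                                                  "assessment_age",
                                                  "pd_duration",
                                                  "durat_pd"),
                              collinearity_threshold = 0.999,
                              test_fraction = 0.20,
                              seed = 1L) {
  stopifnot(
    missing_threshold > 0, missing_threshold < 1,
    collinearity_threshold > 0, collinearity_threshold <= 1,
    test_fraction > 0, test_fraction < 1
  )
  structure(
    list(missing_threshold = missing_threshold,
         onset_blocklist = onset_blocklist,
         collinearity_threshold = collinearity_threshold,
         test_fraction = test_fraction, seed = as.integer(seed)),
    class = "preprocess_config"
  )
}

#' Onset label codes from ages of onset
#'
#' 0 (early) for an onset age strictly between 21 and 50 years, 1 (late)
#' above 50, `NA` for excluded patients (boundary onset of exactly 50,
#' juvenile onset at 21 or below, or missing).
#'
#' @param ao numeric ages of onset
#' @return integer vector of 0/1/`NA`
#' @export
onset_label <- function(ao) {
  ifelse(
    !is.na(ao) & ao > 21 & ao < 50, 0L,
    ifelse(!is.na(ao) & ao > 50, 1L, NA_integer_)
  )
}

#' Assign early/late onset labels and drop excluded patients
#'
#' Early onset (label 0) is an age of onset strictly between 21 and 50
#' years; late onset (label 1) is an age of onset above 50. Patients at the
#' class boundary (onset exactly 50), with juvenile onset (below 22), or
#' with a missing onset age are excluded; juvenile and boundary exclusions
#' are reported separately.
#'
#' @param cohort a `pd_cohort`
#' @return list with `cohort` (retained rows plus a `label` column of 0/1),
#'   and `report` (counts of retained/excluded patients by reason)
#' @export
assign_onset_labels <- function(cohort) {
  data <- cohort$data
  ao <- data$ageonset
  label <- onset_label(ao)
  reason <- rep(NA_character_, nrow(data))
  reason[is.na(ao)] <- "missing_onset_age"
  reason[!is.na(ao) & ao <= 21] <- "juvenile_onset"
  reason[!is.na(ao) & ao == 50] <- "boundary_onset"
  keep <- !is.na(label)
  out <- cohort
  out$data <- data[keep, , drop = FALSE]
  out$data$label <- label[keep]
  report <- list(
    n_input = nrow(data),
    n_retained = sum(keep),
    n_eopd = sum(label == 0L, na.rm = TRUE),
    n_lopd = sum(label == 1L, na.rm = TRUE),
    excluded = table(reason[!keep]),
    excluded_ids = data$patient_id[!keep]
  )
  list(cohort = out, report = report)
}

#' Select model features
#'
#' Three passes over the labeled cohort: (i) drop features whose missing
#' fraction exceeds the threshold, (ii) drop the onset-derived blocklist
#' (ages and disease duration — the label is computed from them), and
#' (iii) a multicollinearity check: for any pair of remaining features with
#' absolute Pearson correlation at or above the threshold on complete
#' cases (exact duplicates included), the later one in column order is
#' dropped. Every drop is reported with its reason.
#'
#' @param cohort a labeled `pd_cohort` (see [assign_onset_labels()])
#' @param config a [preprocess_config()]
#' @return list with `cohort` (reduced columns) and `report` (a tibble of
#'   dropped features with reasons, plus the surviving feature names)
#' @export
select_features <- function(cohort, config = preprocess_config()) {
  data <- cohort$data
  feats <- setdiff(names(data),
                   c("patient_id", "label", config$onset_blocklist))
  dropped <- tibble::tibble(feature = character(0), reason = character(0))
  blocked <- intersect(names(data), config$onset_blocklist)
  dropped <- rbind(dropped, tibble::tibble(
    feature = blocked, reason = "onset_derived"
  ))

  miss <- vapply(feats, function(f) mean(is.na(data[[f]])), numeric(1))
  too_missing <- feats[miss > config$missing_threshold]
  dropped <- rbind(dropped, tibble::tibble(
    feature = too_missing,
    reason = sprintf("missing_fraction_%.3f", miss[match(too_missing, feats)])
  ))
  feats <- setdiff(feats, too_missing)

  # pairwise collinearity on complete cases, later column dropped
  collinear <- character(0)
  if (length(feats) >= 2L) {
    x <- as.matrix(data[, feats])
    r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0
    for (j in seq_along(feats)[-1]) {
      if (feats[j] %in% collinear) next
      earlier <- seq_len(j - 1L)
      earlier <- earlier[!(feats[earlier] %in% collinear)]
      if (any(abs(r[earlier, j]) >= config$collinearity_threshold)) {
        collinear <- c(collinear, feats[j])
      }
    }
  }
  dropped <- rbind(dropped, tibble::tibble(
    feature = collinear, reason = "collinear"
  ))
  feats <- setdiff(feats, collinear)
  if (length(feats) < 2L) {
    stop("fewer than 2 features survive selection")
  }

  out <- cohort
  keep_cols <- intersect(
    c("patient_id", "ageonset", "assessment_age", "gender", feats, "label"),
    names(data)
  )
  out$data <- data[, keep_cols, drop = FALSE]
  attr(out, "model_features") <- feats
  list(cohort = out,
       report = list(dropped = dropped, selected = feats))
}

#' Fit and apply normative-value imputation
#'
#' Normative values are the training-table median for numeric features and
#' mode (ties to the smallest value) for ordinal/binary features. Values
#' are fitted on the training table only and applied to every table passed,
#' so held-out values are never read.
#'
#' @param train training data frame
#' @param ... further data frames imputed with the train-fitted values
#' @param kinds named character vector mapping feature names to kinds
#'   (`"numeric"` gets a median, anything else a mode); features absent
#'   from `kinds` are treated by their storage type
#' @param features columns to impute; defaults to all shared numeric columns
#'   except `patient_id` and `label`
#' @return list with `tables` (imputed data frames, in input order, the
#'   training table first) and `normative_values` (named numeric vector)
#' @export
impute_missing <- function(train, ..., kinds = NULL, features = NULL) {
  others <- list(...)
  features <- features %||% setdiff(names(train), c("patient_id", "label"))
  features <- features[vapply(features, function(f) is.numeric(train[[f]]),
                              logical(1))]
  normative <- vapply(features, function(f) {
    x <- train[[f]]
    if (all(is.na(x))) {
      stop("feature entirely missing in training data: ", f)
    }
    kind <- if (!is.null(kinds) && f %in% names(kinds)) kinds[[f]] else
      if (length(unique(x[!is.na(x)])) > 20L) "numeric" else "categorical"
    if (kind == "numeric") stats::median(x, na.rm = TRUE) else stat_mode(x)
  }, numeric(1))
  fill <- function(tbl) {
    for (f in intersect(features, names(tbl))) {
      tbl[[f]][is.na(tbl[[f]])] <- normative[[f]]
    }
    tbl
  }
  list(tables = lapply(c(list(train), others), fill),
       normative_values = normative)
}

#' Impute a cohort with its own normative values
#'
#' Convenience wrapper used for external validation cohorts, which are
#' imputed with normative values fitted on themselves before rule matching.
#'
#' @param cohort a `pd_cohort`
#' @return the cohort with clinical features imputed
#' @export
impute_cohort <- function(cohort) {
  # ordinal/binary items take a mode; truly numeric scales (ages, the 0-15
  # depression total) take a median
  kinds <- stats::setNames(
    ifelse(cohort$dictionary$kind %in% c("numeric", "integer0_15"),
           "numeric", "categorical"),
    cohort$dictionary$feature
  )
  feats <- setdiff(names(cohort$data), c("patient_id", "label"))
  imp <- impute_missing(cohort$data, kinds = kinds, features = feats)
  out <- cohort
  out$data <- tibble::as_tibble(imp$tables[[1]])
  attr(out, "normative_values") <- imp$normative_values
  out
}

#' Seeded train/test split
#'
#' A plain seeded random split over rows: the training set takes
#' `floor(n * (1 - test_fraction))` rows, the remainder is the test set
#' (381 patients at an 80-20 split give 304 and 77). Class counts per side
#' are attached so imbalance regimes are reproducible.
#'
#' @param data labeled data frame
#' @param config a [preprocess_config()]
#' @return list with `train`, `test`, and `report` (sizes and class counts)
#' @export
split_train_test <- function(data, config = preprocess_config()) {
  n <- nrow(data)
  n_train <- as.integer(floor(n * (1 - config$test_fraction)))
  set.seed(substream_seed(config$seed, 7L))
  idx <- sample.int(n)
  train <- data[sort(idx[seq_len(n_train)]), , drop = FALSE]
  test <- data[sort(idx[-seq_len(n_train)]), , drop = FALSE]
  class_counts <- function(lbl) {
    tb <- table(factor(lbl, levels = 0:1))
    stats::setNames(as.integer(tb), names(tb))
  }
  report <- list(
    n_train = nrow(train), n_test = nrow(test),
    train_classes = class_counts(train$label),
    test_classes = class_counts(test$label)
  )
  list(train = train, test = test, report = report)
}

#' Random oversampling of the minority onset class
#'
#' Minority-class rows are resampled uniformly with replacement until both
#' classes reach the majority count. Every duplicated row keeps its
#' original `patient_id`, so unique-patient counts stay computable
#' downstream; restricting the result to unique patients recovers the
#' original table.
#'
#' @param train labeled data frame with a `label` column of 0/1
#' @param seed integer seed
#' @return the balanced data frame (original rows first, duplicates after)
#' @export
random_oversample <- function(train, seed = 1L) {
  counts <- table(factor(train$label, levels = 0:1))
  if (any(counts == 0L)) {
    stop("both onset classes must be present before oversampling")
  }
  if (counts[["0"]] == counts[["1"]]) return(train)
  minority <- names(counts)[which.min(counts)]
  deficit <- abs(counts[["1"]] - counts[["0"]])
  minority_rows <- which(train$label == as.integer(minority))
  set.seed(substream_seed(seed, 8L))
  extra <- sample(minority_rows, deficit, replace = TRUE)
  rbind(train, train[extra, , drop = FALSE])
}
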