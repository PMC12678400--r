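# Hyperparameter selection by k-fold grid search and model evaluation.

#' Hyperparameter grid for cross-validation
#'
#' Defaults follow the study design: minimum samples per leaf in
#' {10, 12, 14, 16, 18, 20} (at least 10, so every leaf is large enough to
#' be a candidate subtype), maximum depth in {4, 8, 12, 16, 20}, 10 folds.
#'
#' @param min_samples_leaf candidate minimum leaf sizes (each at least 10)
#' @param max_depth candidate depth limits
#' @param k number of folds
#' @param seed integer seed for the fold partition
#' @return a `cv_grid` object
#' @export
cv_grid <- function(min_samples_leaf = c(10L, 12L, 14L, 16L, 18L, 20L),
                    max_depth = c(4L, 8L, 12L, 16L, 20L),
                    k = 10L, seed = 1L) {
  if (any(min_samples_leaf < 10L)) {
    stop("min_samples_leaf candidates must be at least 10")
  }
  structure(
    list(cells = expand.grid(max_depth = as.integer(max_depth),
                             min_samples_leaf = as.integer(min_samples_leaf)),
         k = as.integer(k), seed = as.integer(seed)),
    class = "cv_grid"
  )
}

#' Grid search by k-fold cross-validation over unique patients
#'
#' Folds partition the unique patient ids (never rows), so oversampling
#' duplicates of one patient can never straddle a fold boundary. By default
#' oversampling is applied inside each fold's training portion only and
#' accuracy is measured on the untouched validation fold;
#' `oversample = "before"` reproduces the literal oversample-then-CV
#' reading, in which duplicated minority patients appear in validation
#' folds. Ties between cells break to the smaller depth, then the larger
#' minimum leaf size (the simpler tree). A single-cell grid is returned
#' directly without cross-validating.
#'
#' @param train labeled data frame with `patient_id`, `label` and the model
#'   features
#' @param grid a [cv_grid()]
#' @param features model feature names; defaults to every numeric column
#'   except ids, ages and the label
#' @param oversample `"within_folds"` (default) or `"before"`
#' @return list with `best` (named list `max_depth`, `min_samples_leaf`),
#'   `table` (per-cell mean validation accuracy) and `folds` (the patient
#'   fold assignment)
#' @export
cross_validate_grid <- function(train, grid = cv_grid(), features = NULL,
                                oversample = c("within_folds", "before")) {
  oversample <- match.arg(oversample)
  features <- features %||% setdiff(
    names(train)[vapply(train, is.numeric, logical(1))],
    c("label", "ageonset", "assessment_age")
  )
  cells <- grid$cells
  if (nrow(cells) == 1L) {
    return(list(
      best = list(max_depth = cells$max_depth[1],
                  min_samples_leaf = cells$min_samples_leaf[1]),
      table = tibble::tibble(max_depth = cells$max_depth,
                             min_samples_leaf = cells$min_samples_leaf,
                             mean_accuracy = NA_real_),
      folds = NULL
    ))
  }
  uids <- unique(train$patient_id)
  if (grid$k > length(uids)) {
    stop("more folds than unique patients")
  }
  set.seed(substream_seed(grid$seed, 11L))
  fold_of <- stats::setNames(
    sample(rep(seq_len(grid$k), length.out = length(uids))), uids
  )
  acc <- matrix(NA_real_, nrow(cells), grid$k)
  for (f in seq_len(grid$k)) {
    va_rows <- fold_of[train$patient_id] == f
    tr <- train[!va_rows, , drop = FALSE]
    va <- train[va_rows, , drop = FALSE]
    if (oversample == "within_folds") {
      tr <- random_oversample(tr, seed = substream_seed(grid$seed, 20L + f))
    }
    for (ci in seq_len(nrow(cells))) {
      tree <- fit_tree(tr[, features, drop = FALSE], tr$label,
                       max_depth = cells$max_depth[ci],
                       min_samples_leaf = cells$min_samples_leaf[ci],
                       ids = tr$patient_id)
      pred <- predict(tree, va[, features, drop = FALSE])
      acc[ci, f] <- mean(pred == va$label)
    }
  }
  mean_acc <- rowMeans(acc)
  ord <- order(-mean_acc, cells$max_depth, -cells$min_samples_leaf)
  best <- ord[1]
  list(
    best = list(max_depth = cells$max_depth[best],
                min_samples_leaf = cells$min_samples_leaf[best]),
    table = tibble::tibble(max_depth = cells$max_depth,
                           min_samples_leaf = cells$min_samples_leaf,
                           mean_accuracy = mean_acc),
    folds = fold_of
  )
}

#' Area under the ROC curve by midranks
#'
#' Ranks the scores with ties resolved by the midrank convention;
#' equivalent to counting, over all (positive, negative) pairs, wins plus
#' half of the ties. `NA` when only one class is present.
#'
#' @param scores numeric scores, higher meaning more class-1-like
#' @param y binary 0/1 labels
#' @return AUROC in [0, 1], or `NA`
#' @export
auroc_midrank <- function(scores, y) {
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted tree on labeled data
#'
#' Precision and recall are computed for class 1 (late onset); AUROC ranks
#' patients by their leaf's class-1 training fraction with midrank tie
#' handling, and is reported missing when the data contain one class only.
#'
#' @param tree an `onset_tree`
#' @param data labeled data frame carrying the model features
#' @return named list: `accuracy`, `precision`, `recall`, `auroc`
#' @export
evaluate_tree <- function(tree, data) {
  pred <- predict(tree, data)
  score <- predict(tree, data, type = "prob")
  y <- data$label
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  list(
    accuracy = mean(pred == y),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    auroc = auroc_midrank(score, y)
  )
}
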