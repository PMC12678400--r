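# Labeling, feature selection, imputation, splitting, oversampling.

labeled_toy <- function(ao) {
  make_toy_cohort(tibble::tibble(
    patient_id = sprintf("P%02d", seq_along(ao)),
    ageonset = ao, assessment_age = ao + 5,
    gender = rep_len(c(0, 1), length(ao)),
    itemA = rep_len(0:4, length(ao)), itemB = rep_len(c(1, 2), length(ao))
  ))
}

test_that("onset labels follow the early/late definition with exclusions", {
  res <- assign_onset_labels(labeled_toy(c(45, 50, 51, 21, 22, 49, NA, 20)))
  got <- stats::setNames(res$cohort$data$label, res$cohort$data$patient_id)
  expect_equal(unname(got[c("P01", "P03", "P05", "P06")]), c(0L, 1L, 0L, 0L))
  expect_setequal(res$report$excluded_ids, c("P02", "P04", "P07", "P08"))
  ex <- res$report$excluded
  expect_equal(unname(ex[["boundary_onset"]]), 1)
  expect_equal(unname(ex[["juvenile_onset"]]), 2)
  expect_equal(unname(ex[["missing_onset_age"]]), 1)
  expect_equal(res$report$n_retained, 4)
})

test_that("feature selection drops by missingness, blocklist and collinearity", {
  set.seed(1)
  n <- 100
  data <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:n),
    ageonset = sample(30:70, n, TRUE),
    assessment_age = sample(40:80, n, TRUE),
    gender = sample(0:1, n, TRUE),
    itemA = sample(0:4, n, TRUE),
    itemB = sample(0:4, n, TRUE),
    itemC = sample(0:4, n, TRUE)
  )
  data$itemB[1:16] <- NA            # 16% missing at a 15% threshold
  data$itemD <- data$itemA          # exact duplicate -> |r| = 1
  cohort <- make_toy_cohort(data)
  cohort$data$label <- onset_label(cohort$data$ageonset)
  res <- select_features(cohort)
  expect_setequal(res$report$selected, c("gender", "itemA", "itemC"))
  drops <- res$report$dropped
  expect_true("itemB" %in% drops$feature[grepl("missing", drops$reason)])
  expect_equal(drops$feature[drops$reason == "collinear"], "itemD")
  expect_true(all(c("ageonset", "assessment_age") %in%
                    drops$feature[drops$reason == "onset_derived"]))
})

test_that("a clean synthetic cohort keeps its full clinical feature set", {
  cfg <- generator_config(n_patients = 150, missingness = 0.02, seed = 4)
  cohort <- generate_cohort(cfg)
  lab <- assign_onset_labels(cohort)
  res <- select_features(lab$cohort)
  # 70 rating items + depression score + gender survive; the onset-derived
  # ages are blocked
  expect_length(res$report$selected, 72)
  expect_false(any(c("ageonset", "assessment_age") %in% res$report$selected))
})

test_that("normative values are train-only medians and smallest-value modes", {
  train <- tibble::tibble(ord = c(0, 0, 1, 4, NA))
  held <- tibble::tibble(ord = c(NA, 2))
  res <- impute_missing(train, held, kinds = c(ord = "categorical"))
  expect_equal(res$normative_values[["ord"]], 0)
  expect_equal(res$tables[[1]]$ord, c(0, 0, 1, 4, 0))
  expect_equal(res$tables[[2]]$ord, c(0, 2))

  num <- impute_missing(tibble::tibble(num = c(1, 2, 3, NA)),
                        tibble::tibble(num = c(NA, 9)),
                        kinds = c(num = "numeric"))
  expect_equal(num$normative_values[["num"]], 2)
  expect_equal(num$tables[[2]]$num, c(2, 9))
  # mode ties break to the smallest value
  tie <- impute_missing(tibble::tibble(ord = c(2, 2, 1, 1, NA)),
                        kinds = c(ord = "categorical"))
  expect_equal(tie$normative_values[["ord"]], 1)
  expect_error(impute_missing(tibble::tibble(ord = c(NA_real_, NA))),
               "entirely missing")
})

test_that("held-out values never influence the fitted normative values", {
  set.seed(8)
  train <- tibble::tibble(a = sample(0:4, 30, TRUE), b = rnorm(30))
  train$a[1:4] <- NA
  held1 <- tibble::tibble(a = sample(0:4, 10, TRUE), b = rnorm(10))
  held2 <- held1
  held2$a <- rev(held2$a)
  held2$b <- held2$b * 100
  kinds <- c(a = "categorical", b = "numeric")
  r1 <- impute_missing(train, held1, kinds = kinds)
  r2 <- impute_missing(train, held2, kinds = kinds)
  expect_identical(r1$normative_values, r2$normative_values)
})

test_that("the split is seeded, disjoint, exhaustive and sized by floor", {
  data <- tibble::tibble(patient_id = sprintf("P%03d", 1:381),
                         label = rep_len(0:1, 381))
  cfg <- preprocess_config(seed = 13)
  sp <- split_train_test(data, cfg)
  expect_equal(sp$report$n_train, 304)
  expect_equal(sp$report$n_test, 77)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  expect_setequal(c(sp$train$patient_id, sp$test$patient_id),
                  data$patient_id)
  sp2 <- split_train_test(data, cfg)
  expect_identical(sp$train$patient_id, sp2$train$patient_id)
  small <- split_train_test(data[1:10, ], cfg)
  expect_equal(c(small$report$n_train, small$report$n_test), c(8, 2))
})

test_that("oversampling balances classes and preserves patient identity", {
  set.seed(2)
  train <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:304),
    label = rep(c(1L, 0L), c(197, 107)),
    x = rnorm(304)
  )
  over <- random_oversample(train, seed = 5)
  expect_equal(nrow(over), 394)
  expect_equal(as.vector(table(over$label)), c(197, 197))
  # restricting to unique patients recovers the original table
  expect_equal(over[!duplicated(over$patient_id), ], train)
  # duplicates come only from the minority class
  dup <- over$patient_id[duplicated(over$patient_id)]
  expect_true(all(dup %in% train$patient_id[train$label == 0L]))

  balanced <- tibble::tibble(patient_id = c("A", "B"), label = 0:1)
  expect_identical(random_oversample(balanced), balanced)
  expect_error(random_oversample(tibble::tibble(patient_id = "A",
                                                label = 1L)),
               "both onset classes")
})
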