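# Leaf-to-rule extraction, skew categorization and the three filtering
# criteria.

test_that("a depth-1 tree yields two single-condition rules", {
  train <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:40),
    a = rep(c(0, 4), each = 20),
    label = rep(0:1, each = 20)
  )
  tree <- fit_tree(train[, "a", drop = FALSE], train$label,
                   min_samples_leaf = 5, ids = train$patient_id)
  rules <- extract_candidate_subtypes(tree, train)
  expect_length(rules, 2)
  expect_equal(vapply(rules, function(r) nrow(r$conditions), integer(1)),
               c(1L, 1L))
  expect_equal(rules[[1]]$conditions$op, "<=")
  expect_equal(rules[[2]]$conditions$op, ">")
  expect_equal(rules[[1]]$category, "early")
  expect_equal(rules[[2]]$category, "late")
  expect_equal(rules[[1]]$name, "E1")
  expect_equal(rules[[2]]$name, "L1")
})

test_that("path conditions simplify to the tightest bound per feature", {
  conds <- tibble::tibble(
    feature = c("x", "y", "x", "x"),
    op = c("<=", ">", "<=", ">"),
    threshold = c(3, 1, 1, 0.5)
  )
  simp <- onsettree:::simplify_conditions(conds)
  x_up <- simp[simp$feature == "x" & simp$op == "<=", ]
  x_lo <- simp[simp$feature == "x" & simp$op == ">", ]
  expect_equal(x_up$threshold, 1)   # tightest upper bound
  expect_equal(x_lo$threshold, 0.5)
  expect_equal(nrow(simp), 3)
})

test_that("rule member sets partition the training patients", {
  set.seed(19)
  n <- 300
  train <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:n),
    a = sample(0:4, n, TRUE), b = sample(0:4, n, TRUE),
    c = sample(0:4, n, TRUE)
  )
  train$label <- as.integer(train$a > 2 | train$b <= 1)
  flip <- sample(n, 30)
  train$label[flip] <- 1L - train$label[flip]
  tree <- fit_tree(train[, c("a", "b", "c")], train$label,
                   max_depth = 4, min_samples_leaf = 12,
                   ids = train$patient_id)
  rules <- extract_candidate_subtypes(tree, train)
  members <- lapply(rules, function(r) r$member_ids)
  expect_setequal(unlist(members), train$patient_id)
  expect_equal(sum(lengths(members)), n)  # pairwise disjoint
  # extraction reproduces direct tree routing exactly
  leaf_of <- predict(tree, train[, c("a", "b", "c")], type = "leaf")
  for (r in rules) {
    expect_setequal(r$member_ids, train$patient_id[leaf_of == r$leaf_id])
    expect_setequal(apply_rule(r, train), r$member_ids)
  }
})

test_that("categorization follows the 0.4 impurity cutoff", {
  expect_equal(categorize_subtype(c(0, 15)), "late")
  expect_equal(categorize_subtype(c(2, 18)), "late")   # gini 0.18
  expect_equal(gini_impurity(c(2, 18)), 1 - 0.01 - 0.81)
  expect_equal(categorize_subtype(c(20, 50)), "mixed") # gini 0.408 > 0.4
  expect_equal(categorize_subtype(c(18, 2)), "early")
  expect_equal(categorize_subtype(c(10, 10)), "mixed") # tie, gini 0.5
})

test_that("apply_rule is a conjunction with sane degenerate cases", {
  data <- tibble::tibble(patient_id = c("A", "B", "C"),
                         x = c(0, 2, 4), y = c(1, 1, 0))
  all_rule <- list(conditions = tibble::tibble(
    feature = character(0), op = character(0), threshold = numeric(0)
  ))
  expect_equal(apply_rule(all_rule, data), c("A", "B", "C"))
  contradictory <- list(conditions = tibble::tibble(
    feature = c("x", "x"), op = c("<=", ">"), threshold = c(1, 3)
  ))
  expect_length(apply_rule(contradictory, data), 0)
  ghost <- list(conditions = tibble::tibble(
    feature = "zz", op = ">", threshold = 0
  ))
  expect_error(apply_rule(ghost, data), "zz")
})

test_that("a fully adherent planted rule matches all its members", {
  rule <- tibble::tibble(feature = c("updrs3_10", "updrs1_11"),
                         op = c(">", ">"), threshold = c(2, 2))
  cfg <- generator_config(
    n_patients = 500, missingness = 0, seed = 31,
    planted_subtypes = list(
      planted_subtype(rule, prevalence = 0.12, onset_skew = 0.9,
                      adherence = 1.0)
    )
  )
  cohort <- generate_cohort(cfg)
  matched <- apply_rule(list(conditions = rule), cohort$data)
  expect_true(all(cohort$planted[[1]]$member_ids %in% matched))
})

test_that("criteria 1 counts unique patients, not oversampled rows", {
  r10 <- list(member_ids = sprintf("P%02d", 1:10))
  expect_true(criteria1_size(r10)$pass)
  r9 <- list(member_ids = sprintf("P%02d", 1:9))
  expect_false(criteria1_size(r9)$pass)
  # 19 rows but only 9 unique patients: uniqueness is the ground truth
  r_dup <- list(member_ids = c(sprintf("P%02d", 1:9),
                               rep(sprintf("P%02d", 1:5), 2)))
  expect_false(criteria1_size(r_dup)$pass)
  expect_equal(criteria1_size(r_dup)$n_unique, 9)
})

test_that("the oversampling-adjusted leaf threshold follows the imbalance", {
  r <- oversampled_min_leaf(197, 107, 10)
  expect_equal(r$raw, 197 / 107 * 10)
  expect_equal(round(r$raw, 1), 18.4)
  expect_equal(r$ceiling, 19L)
  expect_equal(oversampled_min_leaf(100, 100, 10)$raw, 10)
  expect_equal(oversampled_min_leaf(300, 100, 10)$raw, 30)
})

test_that("criteria-2 thresholds are ceilings of the class fraction", {
  expect_equal(criteria2_threshold("early", 68, 321, 402), 4L)
  expect_equal(criteria2_threshold("late", 68, 321, 402), 17L)
  expect_equal(criteria2_threshold("mixed", 68, 321, 402), 21L)
  expect_equal(criteria2_threshold("late", 68, 321, 402, fraction = 0), 0L)
})

test_that("criteria 2 matches against the category's external class", {
  external <- tibble::tibble(
    patient_id = sprintf("V%03d", 1:100),
    x = rep(c(0, 4), 50),
    label = c(rep(0L, 30), rep(1L, 60), rep(NA_integer_, 10))
  )
  rule <- list(conditions = tibble::tibble(feature = "x", op = ">",
                                           threshold = 2),
               category = "late")
  c2 <- criteria2_external(rule, external, fraction = 0.05)
  expect_equal(c2$n_eopd, 30)
  expect_equal(c2$n_lopd, 60)
  expect_equal(c2$n_total, 100)
  expect_equal(c2$matched_total, 50)
  expect_equal(c2$threshold, 3L)  # ceiling(0.05 * 60)
  expect_true(c2$pass)
  rule$category <- "mixed"
  c2m <- criteria2_external(rule, external, fraction = 0.05)
  expect_equal(c2m$threshold, 5L)  # ceiling(0.05 * 100), full cohort
  expect_equal(c2m$matches, 50)
  expect_error(criteria2_external(rule, external[0, ]), "empty")
})

test_that("precision and the class-prior threshold gate early/late rules", {
  expect_equal(round(subtype_precision(20, 50), 3), 0.286)
  c3 <- criteria3_precision("early", 20, 50, 68, 321)
  expect_equal(round(c3$threshold, 3), 0.175)
  expect_true(c3$pass)
  c3l <- criteria3_precision("late", 6, 39, 68, 321)
  expect_equal(round(c3l$precision, 3), 0.867)
  expect_equal(round(c3l$threshold, 3), 0.825)
  expect_true(c3l$pass)
  none <- criteria3_precision("early", 0, 0, 68, 321)
  expect_false(none$pass)
  expect_equal(none$reason, "no external matches")
  zero <- criteria3_precision("early", 0, 5, 68, 321)
  expect_false(zero$pass)
  mixed <- criteria3_precision("mixed", NA, NA, 68, 321)
  expect_false(mixed$applicable)
  expect_true(mixed$pass)
})

test_that("filtering is monotone in its thresholds", {
  set.seed(77)
  cfg <- generator_config(n_patients = 400, seed = 77)
  pair <- generate_paired_cohorts(cfg)
  res <- run_subtyping_pipeline(
    pair$training, pair$validation,
    grid = cv_grid(min_samples_leaf = 10L, max_depth = 6L),
    config = preprocess_config(seed = 77)
  )
  base <- res$filter$survivors
  ext <- res$external
  for (frac in c(0.10, 0.25, 1)) {
    tighter <- run_filter_pipeline(res$rules, ext, fraction = frac)
    expect_true(all(tighter$survivors %in% base),
                label = paste("fraction", frac))
  }
  stricter <- run_filter_pipeline(res$rules, ext, min_unique = 40L)
  expect_true(all(stricter$survivors %in% base))
  nothing <- run_filter_pipeline(res$rules, ext, fraction = 1,
                                 min_unique = 10000L)
  expect_length(nothing$survivors, 0)
})
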