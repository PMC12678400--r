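# The CART core: impurity arithmetic, split search against an exhaustive
# oracle, structural invariants, importance, serialization, and agreement
# with an independent reference implementation.

test_that("gini impurity matches hand arithmetic", {
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(20, 50)), 1 - (2 / 7)^2 - (5 / 7)^2)
  expect_error(gini_impurity(c(0, 0)), "empty")
})

test_that("pure labels give a single leaf; a 1-D step is split at 2.5", {
  t0 <- fit_tree(matrix(1:6, ncol = 1), rep(1L, 6), min_samples_leaf = 1)
  expect_true(t0$root$is_leaf)
  expect_equal(t0$root$label, 1L)

  t1 <- fit_tree(matrix(1:4, ncol = 1), c(0L, 0L, 1L, 1L),
                 min_samples_leaf = 1)
  expect_false(t1$root$is_leaf)
  expect_equal(t1$root$threshold, 2.5)
  expect_true(t1$root$left$is_leaf && t1$root$right$is_leaf)
  expect_equal(mean(predict(t1, matrix(1:4, ncol = 1)) ==
                      c(0L, 0L, 1L, 1L)), 1)
})

test_that("the first split agrees with the exhaustive oracle on tiny data", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:8, 1)
    p <- sample(1:3, 1)
    x <- matrix(sample(0:4, n * p, TRUE), n, p)
    y <- sample(0:1, n, TRUE)
    if (length(unique(y)) < 2) next
    got <- onsettree:::best_split(x, y, 1L)
    want <- oracle_best_split(x, y, 1L)
    if (is.null(want)) {
      expect_null(got, label = paste("seed", seed))
    } else {
      expect_equal(got$feature, want$feature, label = paste("seed", seed))
      expect_equal(got$threshold, want$threshold,
                   label = paste("seed", seed))
      expect_equal(got$decrease, want$decrease, tolerance = 1e-12)
    }
  }
})

test_that("fitted trees respect depth, leaf-size and impurity invariants", {
  set.seed(42)
  n <- 400
  x <- data.frame(a = sample(0:4, n, TRUE), b = sample(0:4, n, TRUE),
                  c = rnorm(n))
  y <- as.integer(x$a > 2 | (x$b <= 1 & x$c > 0))
  flip <- sample(n, 40)  # label noise
  y[flip] <- 1L - y[flip]
  tree <- fit_tree(x, y, max_depth = 4, min_samples_leaf = 15)

  check <- function(node) {
    expect_gte(node$gini, 0)
    expect_lte(node$gini, 0.5)
    if (node$is_leaf) {
      expect_gte(node$n, 15)
      expect_lte(node$depth, 4)
      return(invisible(NULL))
    }
    expect_equal(node$counts, node$left$counts + node$right$counts)
    w <- (node$left$n * node$left$gini + node$right$n * node$right$gini) /
      node$n
    expect_lt(w, node$gini)  # accepted splits strictly decrease impurity
    check(node$left)
    check(node$right)
  }
  check(tree$root)
})

test_that("gini importance is normalized and ignores unused features", {
  x <- data.frame(a = c(1, 2, 3, 4, 5, 6), b = c(9, 9, 9, 9, 9, 9))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  tree <- fit_tree(x, y, min_samples_leaf = 1)
  imp <- gini_feature_importance(tree)
  expect_equal(unname(imp["a"]), 1)
  expect_equal(unname(imp["b"]), 0)

  # two-split tree with hand-computed decreases:
  # root (4,2), g = 4/9; splits a<=2.5 (tie with b<=0.5, lower index wins):
  # left (2,0) pure, right (2,2) g=.5 -> decrease 1/9 at weight 1
  # right node has constant a, splits b<=0.5 into two pure halves:
  # decrease .5 at weight 4/6
  x2 <- data.frame(a = c(1, 2, 3, 3, 3, 3), b = c(0, 0, 0, 0, 1, 1))
  y2 <- c(0L, 0L, 1L, 1L, 0L, 0L)
  tree2 <- fit_tree(x2, y2, min_samples_leaf = 1, max_depth = 2)
  expect_equal(tree2$root$feature, "a")
  expect_equal(tree2$root$right$feature, "b")
  imp2 <- gini_feature_importance(tree2)
  raw_a <- 1 * (1 / 9)
  raw_b <- (4 / 6) * 0.5
  expect_equal(unname(imp2["a"]), raw_a / (raw_a + raw_b))
  expect_equal(unname(imp2["b"]), raw_b / (raw_a + raw_b))
  expect_equal(sum(imp2), 1)

  # permuting an unused feature's values changes nothing
  x3 <- x
  x3$b <- rev(x3$b)
  expect_equal(gini_feature_importance(fit_tree(x3, y, min_samples_leaf = 1)),
               imp)

  stump <- fit_tree(matrix(1, 4, 1), rep(1L, 4), min_samples_leaf = 1)
  imp0 <- gini_feature_importance(stump)
  expect_equal(sum(imp0), 0)
  expect_true(attr(imp0, "no_splits"))
})

test_that("training predictions match an independent CART implementation", {
  skip_if_not_installed("rpart")
  for (seed in c(3, 14, 27, 58)) {
    set.seed(seed)
    n <- 80
    x <- data.frame(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
    y <- as.integer(x$f1 + 0.5 * x$f2 + rnorm(n, sd = 0.5) > 0)
    if (length(unique(y)) < 2) next
    ours <- fit_tree(x, y, max_depth = 3, min_samples_leaf = 8)
    ref <- rpart::rpart(
      factor(y) ~ ., data = cbind(x, y = y),
      method = "class",
      control = rpart::rpart.control(minsplit = 2, minbucket = 8,
                                     maxdepth = 3, cp = 0, xval = 0)
    )
    ref_pred <- as.integer(as.character(predict(ref, x, type = "class")))
    expect_equal(predict(ours, x), ref_pred, label = paste("seed", seed))
  }
})

test_that("trees survive a JSON round trip", {
  set.seed(6)
  x <- data.frame(a = sample(0:4, 120, TRUE), b = sample(0:4, 120, TRUE))
  y <- as.integer(x$a > 2)
  y[1:10] <- 1L - y[1:10]
  tree <- fit_tree(x, y, max_depth = 3, min_samples_leaf = 10,
                   ids = sprintf("P%03d", rep(1:60, 2)))
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tree, path)
  back <- tree_from_json(path)
  expect_equal(predict(back, x), predict(tree, x))
  expect_equal(predict(back, x, type = "prob"), predict(tree, x, "prob"))
  expect_equal(back$features, tree$features)
  expect_equal(back$root$unique_counts, tree$root$unique_counts)
})
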