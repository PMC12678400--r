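#!/usr/bin/env Rscript
# Stage 4: hyperparameter search and the final onset classifier.
#
# A reduced grid (depth 4/8, minimum leaf 10/20) is searched by 10-fold
# cross-validation over unique patients, oversampling applied inside each
# fold's training portion; the winning cell refits on the full oversampled
# training split. Metrics and normalized Gini importances follow.

suppressPackageStartupMessages(library(onsettree))

in_dir <- "results/preprocess"
out_dir <- "results/model"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

train <- tibble::as_tibble(utils::read.csv(
  file.path(in_dir, "train_oversampled.csv"),
  colClasses = c(patient_id = "character")
))
test <- tibble::as_tibble(utils::read.csv(
  file.path(in_dir, "test.csv"), colClasses = c(patient_id = "character")
))
features <- jsonlite::fromJSON(
  file.path(in_dir, "reports.json")
)$selected_features

# fold search runs on the un-duplicated table so folds stay leak-free
train_unique <- train[!duplicated(train$patient_id), ]
grid <- cv_grid(min_samples_leaf = c(10L, 20L), max_depth = c(4L, 8L),
                k = 10L, seed = 42L)
cv <- cross_validate_grid(train_unique, grid, features = features)
cat("cross-validated cells:\n")
print(as.data.frame(cv$table))
cat(sprintf("best: max_depth %d, min_samples_leaf %d\n",
            cv$best$max_depth, cv$best$min_samples_leaf))

tree <- fit_tree(train[, features], train$label,
                 max_depth = cv$best$max_depth,
                 min_samples_leaf = cv$best$min_samples_leaf,
                 ids = train$patient_id)
print(tree)
m <- evaluate_tree(tree, test)
cat(sprintf(
  "test: accuracy %.3f, precision %.3f, recall %.3f, AUROC %.3f\n",
  m$accuracy, m$precision, m$recall, m$auroc
))

imp <- sort(gini_feature_importance(tree), decreasing = TRUE)
top <- imp[imp > 0][1:min(10, sum(imp > 0))]
cat("top feature importances:\n")
print(round(top, 3))

tree_to_json(tree, file.path(out_dir, "tree.json"))
utils::write.csv(
  data.frame(feature = names(imp), importance = unname(imp)),
  file.path(out_dir, "importance.csv"), row.names = FALSE
)
jsonlite::write_json(
  list(best = cv$best, cv_table = cv$table, test_metrics = m),
  file.path(out_dir, "metrics.json"), auto_unbox = TRUE, pretty = TRUE
)
cat("wrote", out_dir, "\n")
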