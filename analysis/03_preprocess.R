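#!/usr/bin/env Rscript
# Stage 3: onset labels, feature selection, split, imputation, oversampling.
#
# Training patients get early/late labels from onset age (boundary and
# juvenile onsets excluded), features are reduced (missingness threshold,
# onset-derived blocklist, collinearity check), an 80-20 split is drawn,
# normative values are fitted on the training split only, and the minority
# class is oversampled to balance.

suppressPackageStartupMessages(library(onsettree))

dir <- "results/cohorts"
out_dir <- "results/preprocess"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cfg <- preprocess_config(seed = 42L)

training <- read_cohort(file.path(dir, "training.csv"))
lab <- assign_onset_labels(training)
cat(sprintf("labels: %d retained (%d early, %d late), %d excluded\n",
            lab$report$n_retained, lab$report$n_eopd, lab$report$n_lopd,
            lab$report$n_input - lab$report$n_retained))

sel <- select_features(lab$cohort, cfg)
cat(sprintf("features: %d selected, %d dropped\n",
            length(sel$report$selected), nrow(sel$report$dropped)))

sp <- split_train_test(sel$cohort$data, cfg)
cat(sprintf("split: %d train / %d test; training classes %s\n",
            sp$report$n_train, sp$report$n_test,
            paste(sp$report$train_classes, collapse = "/")))

kinds <- stats::setNames(
  ifelse(training$dictionary$kind %in% c("numeric", "integer0_15"),
         "numeric", "categorical"),
  training$dictionary$feature
)
imp <- impute_missing(sp$train, sp$test, kinds = kinds,
                      features = sel$report$selected)
train <- imp$tables[[1]]
test <- imp$tables[[2]]

over <- random_oversample(train, seed = cfg$seed)
cat(sprintf("oversampled training: %d rows (%s), %d unique patients\n",
            nrow(over),
            paste(table(over$label), collapse = "/"),
            length(unique(over$patient_id))))

utils::write.csv(over, file.path(out_dir, "train_oversampled.csv"),
                 row.names = FALSE)
utils::write.csv(test, file.path(out_dir, "test.csv"), row.names = FALSE)
jsonlite::write_json(
  list(
    labels = lab$report[c("n_input", "n_retained", "n_eopd", "n_lopd")],
    excluded_ids = lab$report$excluded_ids,
    dropped_features = sel$report$dropped,
    selected_features = sel$report$selected,
    split = sp$report,
    normative_values = as.list(imp$normative_values)
  ),
  file.path(out_dir, "reports.json"),
  auto_unbox = TRUE, pretty = TRUE
)
cat("wrote", out_dir, "\n")
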