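#!/usr/bin/env Rscript
# Stage 1: simulate the paired study cohorts.
#
# The access-controlled training and validation cohorts are stood in for by
# synthetic ones: ~70 ordinal rating items, a 0-15 depression score, gender,
# a 2:1 late:early onset mix, low per-feature missingness, a validation arm
# shifted 5 years older, and two planted conjunction-of-conditions subtypes
# (one late-skewed, one early-skewed). The validation cohort is written
# under its own "mds_"-prefixed variable names so stage 2 has a real
# harmonization job to do.

suppressPackageStartupMessages(library(onsettree))

out_dir <- "results/cohorts"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 42L

cfg <- generator_config(n_patients = 1500, seed = seed)
pair <- generate_paired_cohorts(cfg)

# validation cohort gets its own naming scheme, recorded in a feature map
feats <- setdiff(names(pair$validation$data),
                 c("patient_id", "ageonset", "assessment_age", "gender"))
map <- tibble::tibble(source = feats, target = paste0("mds_", feats),
                      kind = "exact", derivation = NA_character_)
class(map) <- c("feature_map", class(map))
write_feature_map(map, file.path(out_dir, "feature_map.tsv"))
validation_mds <- apply_feature_map(pair$validation, map, "forward")

write_cohort(pair$training, file.path(out_dir, "training.csv"))
write_cohort(validation_mds, file.path(out_dir, "validation_mds.csv"))

# ground-truth planted membership, for the final recovery check
jsonlite::write_json(
  lapply(pair$training$planted, function(p) {
    list(conditions = p$conditions, member_ids = p$member_ids)
  }),
  file.path(out_dir, "planted_training.json")
)

cat(sprintf(
  "simulated %d + %d patients (%d clinical features); %d planted subtypes\n",
  nrow(pair$training$data), nrow(validation_mds$data), length(feats),
  length(pair$training$planted)
))
cat(sprintf(
  "validation cohort is %.1f years older at assessment (configured shift: %d)\n",
  mean(validation_mds$data$assessment_age) -
    mean(pair$training$data$assessment_age),
  cfg$demographic_shift_years
))
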