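#!/usr/bin/env Rscript
# Stage 2: harmonize the validation cohort onto the training schema.
#
# Subtype rules will be learned on training variable names, so the
# validation cohort's "mds_"-prefixed columns are mapped back through the
# feature map (the reverse direction of the map written in stage 1). The
# packaged cross-study map is loaded too, as a reference for what a real
# two-dictionary mapping looks like (exact renames plus one-way arithmetic
# derivations).

suppressPackageStartupMessages(library(onsettree))

dir <- "results/cohorts"
map <- load_feature_map(file.path(dir, "feature_map.tsv"))
validation_mds <- read_cohort(file.path(dir, "validation_mds.csv"))

harmonized <- apply_feature_map(validation_mds, map, "reverse")
write_cohort(harmonized, file.path(dir, "validation.csv"))

training <- read_cohort(file.path(dir, "training.csv"))
shared <- intersect(clinical_features(training),
                    clinical_features(harmonized))
cat(sprintf("harmonized validation cohort: %d shared clinical features\n",
            length(shared)))

ref_map <- lrrk2_mds_feature_map()
cat(sprintf(
  "reference cross-study map: %d entries (%d exact, %d derived)\n",
  nrow(ref_map), sum(ref_map$kind == "exact"), sum(ref_map$kind == "derived")
))
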