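#!/usr/bin/env Rscript
# Stage 6: characterization of the surviving subtypes.
#
# Demographic summaries per subtype (and the whole-cohort reference row),
# distinguishable features (mean deviating from the overall mean by more
# than 0.1), published check-sheet replay, and agreement with an external
# clustering. The clustering here is a k-means run over the imputed
# features, standing in for externally supplied cluster label files; the
# comparison machinery (Rand index, overlap table) is the object of
# interest, not the clustering itself.

suppressPackageStartupMessages(library(onsettree))

out_dir <- "results/characterization"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
set.seed(42L)

training <- read_cohort("results/cohorts/training.csv")
full <- impute_cohort(training)$data
full$label <- onset_label(full$ageonset)
rules <- jsonlite::fromJSON("results/subtypes/rules.json",
                            simplifyVector = FALSE)
report <- utils::read.csv("results/subtypes/filter_report.csv")
survivors <- report$name[report$final_pass]

members <- lapply(rules, function(r) {
  conds <- tibble::as_tibble(as.data.frame(
    lapply(do.call(rbind, lapply(r$conditions, as.data.frame)), unlist)
  ))
  apply_rule(list(conditions = conds), full)
})
names(members) <- vapply(rules, `[[`, "", "name")
members <- members[survivors]

# demographic summary, one row per surviving subtype plus the full cohort
demo <- do.call(rbind, c(
  lapply(names(members), function(nm) {
    cbind(subtype = nm, summarize_subtype(members[[nm]], full))
  }),
  list(cbind(subtype = "Overall",
             summarize_subtype(full$patient_id, full)))
))
utils::write.csv(demo, file.path(out_dir, "subtype_demographics.csv"),
                 row.names = FALSE)
cat("subtype demographics:\n")
print(as.data.frame(demo[, c("subtype", "n", "assessment_age_mean",
                             "ageonset_mean", "pd_duration")]),
      digits = 4)

# distinguishable features over the clinical items
items <- setdiff(clinical_features(training), "gender")
sub_means <- vapply(members, function(ids) {
  colMeans(full[full$patient_id %in% ids, items])
}, numeric(length(items)))
overall_means <- colMeans(full[, items])
dist <- distinguishable_features(sub_means, overall_means, delta = 0.1)
distinguishers <- names(which(dist$set_distinguisher))
utils::write.csv(
  data.frame(feature = items, n_flagged = dist$n_flagged,
             set_distinguisher = dist$set_distinguisher),
  file.path(out_dir, "distinguishable_features.csv"), row.names = FALSE
)
cat(sprintf("%d set-level distinguishable features (top: %s)\n",
            length(distinguishers),
            paste(utils::head(distinguishers, 5), collapse = ", ")))

# published check-sheet replay: the study's three diagnostic markers
cs <- reference_subtype_profile()$checksheet
m <- as.matrix(cs[, c("E4", "M3", "M7", "L1", "L2", "L4")])
rownames(m) <- cs$feature
ref_dist <- distinguishable_features(m, cs$Overall, delta = 0.1)
cat(sprintf(
  "published replay: DCASYMM flags %d/6 subtypes; DCPD10Y %d/6; DCPOSINS %d/6\n",
  ref_dist$n_flagged["DCASYMM"], ref_dist$n_flagged["DCPD10Y"],
  ref_dist$n_flagged["DCPOSINS"]
))

# external clustering stand-in: k-means labels over the imputed items
km <- stats::kmeans(scale(as.matrix(full[, items])), centers = 8,
                    nstart = 5, iter.max = 50)
labels <- tibble::tibble(patient_id = full$patient_id,
                         label = km$cluster)
utils::write.csv(labels, file.path(out_dir, "cluster_labels.csv"),
                 row.names = FALSE)

subtype_label <- rep("unassigned", nrow(full))
for (nm in names(members)) {
  subtype_label[full$patient_id %in% members[[nm]]] <- nm
}
ri <- rand_index(subtype_label, labels$label)
cat(sprintf("Rand index, subtypes vs k-means clustering: %.3f\n", ri))

clusters <- split(labels$patient_id, labels$label)
overlap <- cluster_overlap(members, clusters)
utils::write.csv(overlap, file.path(out_dir, "cluster_overlap.csv"),
                 row.names = FALSE)
cat(sprintf("%d (subtype, cluster) pairs overlap by 10+ patients\n",
            nrow(overlap)))
cat("wrote", out_dir, "\n")
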