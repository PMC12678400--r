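# Post-hoc description of final subtypes: demographic summaries, binary
# check-sheet ratios, the distinguishable-feature statistic, and agreement
# with externally produced clusterings.

#' Summarize one subtype
#'
#' Means and sample (n-1) standard deviations of assessment age and onset
#' age over the member patients, gender counts, and the disease duration as
#' the difference of the two reported means. Extra feature means can be
#' requested. A single-member subtype reports an sd of 0, flagged in
#' `sd_flagged`.
#'
#' @param member_ids patient ids of the subtype
#' @param data cohort table (one row per patient)
#' @param features optional extra features to average
#' @return one-row tibble
#' @export
summarize_subtype <- function(member_ids, data, features = NULL) {
  rows <- data[data$patient_id %in% member_ids, , drop = FALSE]
  if (nrow(rows) == 0L) stop("subtype has no members in the cohort table")
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  out <- tibble::tibble(
    n = nrow(rows),
    assessment_age_mean = mean(rows$assessment_age),
    assessment_age_sd = sd0(rows$assessment_age),
    ageonset_mean = mean(rows$ageonset),
    ageonset_sd = sd0(rows$ageonset),
    n_male = sum(rows$gender == 1, na.rm = TRUE),
    n_female = sum(rows$gender == 0, na.rm = TRUE),
    pd_duration = mean(rows$assessment_age) - mean(rows$ageonset),
    sd_flagged = nrow(rows) < 2L
  )
  for (f in features) {
    out[[paste0(f, "_mean")]] <- mean(rows[[f]], na.rm = TRUE)
  }
  out
}

#' Positive-score ratios of binary check-sheet features
#'
#' For every binary feature with less than `max_missing` missing data in
#' the cohort, the ratio of members with a positive (1) score to the
#' subtype's full patient count; missing member values count as
#' non-positive.
#'
#' @param member_ids patient ids of the subtype
#' @param data cohort table
#' @param features binary 0/1 feature names
#' @param max_missing exclusion threshold on the cohort-level missing
#'   fraction (default 0.30)
#' @return tibble with `feature`, `ratio`, and the cohort missing fraction
#' @export
checksheet_ratios <- function(member_ids, data, features,
                              max_missing = 0.30) {
  rows <- data[data$patient_id %in% member_ids, , drop = FALSE]
  miss <- vapply(features, function(f) mean(is.na(data[[f]])), numeric(1))
  kept <- features[miss < max_missing]
  tibble::tibble(
    feature = kept,
    ratio = vapply(kept, function(f) {
      sum(rows[[f]] == 1, na.rm = TRUE) / nrow(rows)
    }, numeric(1), USE.NAMES = FALSE),
    cohort_missing = unname(miss[kept])
  )
}

#' Distinguishable features across subtypes
#'
#' A feature distinguishes a subtype when its subtype mean differs from the
#' overall cohort mean by more than `delta`; it distinguishes the subtype
#' set when it is a distinguisher for at least `set_fraction` of the
#' subtypes.
#'
#' @param subtype_means numeric matrix, features in rows, subtypes in
#'   columns
#' @param overall_means numeric vector, one entry per feature row
#' @param delta absolute mean-difference threshold (default 0.1)
#' @param set_fraction fraction of subtypes required for a set-level
#'   distinguisher (default 0.5)
#' @return list with `flags` (logical matrix), `n_flagged` (per feature)
#'   and `set_distinguisher` (logical per feature)
#' @export
distinguishable_features <- function(subtype_means, overall_means,
                                     delta = 0.1, set_fraction = 0.5) {
  subtype_means <- as.matrix(subtype_means)
  stopifnot(nrow(subtype_means) == length(overall_means))
  flags <- abs(subtype_means - overall_means) > delta
  n_flagged <- rowSums(flags)
  list(
    flags = flags,
    n_flagged = n_flagged,
    set_distinguisher = n_flagged >= set_fraction * ncol(subtype_means)
  )
}

#' Rand index between two partitions
#'
#' The unadjusted 1971 form: the fraction of patient pairs on which the
#' two labelings agree (placed together in both, or apart in both).
#' Invariant to label renaming.
#'
#' @param labels_a,labels_b equal-length label vectors over the same
#'   patients
#' @return value in [0, 1]
#' @export
rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length")
  }
  n <- length(labels_a)
  if (n < 2L) return(1)
  tab <- table(labels_a, labels_b)
  sum_sq <- sum(tab^2)
  sum_a <- sum(rowSums(tab)^2)
  sum_b <- sum(colSums(tab)^2)
  # agreements = C(n,2) - [ (sum_a - sum_sq)/2 + (sum_b - sum_sq)/2 ]
  (choose(n, 2) - (sum_a + sum_b - 2 * sum_sq) / 2) / choose(n, 2)
}

#' Overlap between subtypes and external clusters
#'
#' All (subtype, cluster) pairs sharing at least `min_overlap` patients.
#' Clusters smaller than `min_cluster` are dropped before comparison;
#' unassigned/noise labels are treated as their own group by the caller.
#'
#' @param subtype_members named list of patient-id vectors
#' @param cluster_members named list of patient-id vectors
#' @param min_overlap minimum intersection size (default 10)
#' @param min_cluster minimum cluster size to enter the comparison
#'   (default 10)
#' @return tibble with `subtype`, `cluster`, `overlap`
#' @export
cluster_overlap <- function(subtype_members, cluster_members,
                            min_overlap = 10L, min_cluster = 10L) {
  cluster_members <- Filter(function(m) length(m) >= min_cluster,
                            cluster_members)
  rows <- list()
  for (s in names(subtype_members)) {
    for (k in names(cluster_members)) {
      ov <- length(intersect(subtype_members[[s]], cluster_members[[k]]))
      if (ov >= min_overlap) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subtype = s, cluster = k, overlap = ov
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(subtype = character(0), cluster = character(0),
                          overlap = integer(0)))
  }
  do.call(rbind, rows)
}

#' Read external cluster labels
#'
#' Two-column CSV (`patient_id`, `label`); noise/unassigned markers (e.g.
#' -1) are kept as their own label group.
#'
#' @param path CSV path
#' @return tibble with `patient_id` and `label`
#' @export
read_cluster_labels <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(patient_id = "character"))
  if (!all(c("patient_id", "label") %in% names(tab))) {
    stop("cluster label file must have columns patient_id, label")
  }
  tibble::as_tibble(tab[, c("patient_id", "label")])
}
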