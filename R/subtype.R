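# Leaf-to-rule extraction and the three-stage subtype filter.
#
# Each leaf of the fitted tree is a candidate subtype: the conjunction of
# the feature conditions along its root-to-leaf path. Candidates are
# categorized by the onset-class skew of their unique training members
# (Gini impurity at most 0.4 means a clear early or late majority) and then
# filtered: (1) at least 10 unique training patients, (2) enough matches in
# the external cohort's corresponding onset class, (3) precision above the
# external class prior (early/late candidates only).

#' Categorize a candidate subtype by onset skew
#'
#' @param unique_counts `c(n_early, n_late)` over unique member patients
#' @param gini_cutoff impurity at or below which the majority class names
#'   the category (default 0.4)
#' @return `"early"`, `"late"`, or `"mixed"`
#' @export
categorize_subtype <- function(unique_counts, gini_cutoff = 0.4) {
  g <- gini_impurity(unique_counts)
  if (g > gini_cutoff) return("mixed")
  if (unique_counts[1] > unique_counts[2]) "early" else "late"
}

#' Extract candidate subtype rules from a fitted tree
#'
#' One rule per leaf, in left-to-right leaf order. Along each path only the
#' tightest bound per feature is kept (the smallest upper bound of the
#' `<=` conditions, the largest lower bound of the `>` conditions). Member
#' ids are the unique training patients routed to the leaf; the reported
#' class counts, Gini impurity and category are computed over unique
#' patients, so oversampling duplicates cannot bias the skew (set
#' `unique_members = FALSE` for raw row counts). Names are the category
#' initial (E/L/M) plus an ordinal in leaf order within the category.
#'
#' @param tree an `onset_tree` fitted with patient `ids`
#' @param train the labeled training table the tree was fitted on
#'   (oversampled rows included)
#' @param unique_members count members and skew over unique patients
#'   (default) or over raw rows
#' @return list of `subtype_rule` objects
#' @export
extract_candidate_subtypes <- function(tree, train, unique_members = TRUE) {
  rules <- list()
  walk <- function(node, conds, depth) {
    if (node$is_leaf) {
      rules[[length(rules) + 1L]] <<- list(
        leaf_id = node$id, depth = depth, conditions = conds
      )
      return(invisible(NULL))
    }
    left_conds <- rbind(conds, tibble::tibble(
      feature = node$feature, op = "<=", threshold = node$threshold
    ))
    right_conds <- rbind(conds, tibble::tibble(
      feature = node$feature, op = ">", threshold = node$threshold
    ))
    walk(node$left, left_conds, depth + 1L)
    walk(node$right, right_conds, depth + 1L)
  }
  empty <- tibble::tibble(feature = character(0), op = character(0),
                          threshold = numeric(0))
  walk(tree$root, empty, 0L)

  out <- lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    conds <- simplify_conditions(r$conditions)
    match_rows <- which(apply_rule_matrix(conds, train))
    members <- train[match_rows, , drop = FALSE]
    if (unique_members) {
      members <- members[!duplicated(members$patient_id), , drop = FALSE]
    }
    counts <- c(sum(members$label == 0L), sum(members$label == 1L))
    structure(
      list(
        rule_id = i, leaf_id = r$leaf_id, name = NA_character_,
        conditions = conds, depth = r$depth,
        member_ids = members$patient_id,
        unique_counts = counts,
        gini = if (sum(counts) > 0) gini_impurity(counts) else NA_real_,
        category = if (sum(counts) > 0) categorize_subtype(counts)
                   else "mixed"
      ),
      class = "subtype_rule"
    )
  })

  # E/L/M names numbered in left-to-right leaf order within each category
  for (cat in c("early", "late", "mixed")) {
    idx <- which(vapply(out, function(r) r$category, character(1)) == cat)
    for (k in seq_along(idx)) {
      out[[idx[k]]]$name <- paste0(toupper(substr(cat, 1, 1)), k)
    }
  }
  out
}

# Keep only the tightest lower/upper bound per feature.
simplify_conditions <- function(conds) {
  if (nrow(conds) == 0L) return(conds)
  pieces <- lapply(split(conds, conds$feature), function(fc) {
    keep <- list()
    ups <- fc[fc$op == "<=", ]
    los <- fc[fc$op == ">", ]
    if (nrow(ups) > 0L) {
      keep <- c(keep, list(ups[which.min(ups$threshold), ]))
    }
    if (nrow(los) > 0L) {
      keep <- c(keep, list(los[which.max(los$threshold), ]))
    }
    do.call(rbind, keep)
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  # preserve first-appearance order of features along the path
  res[order(match(res$feature, unique(conds$feature)), res$op), , drop = FALSE]
}

apply_rule_matrix <- function(conds, data) {
  ok <- rep(TRUE, nrow(data))
  for (i in seq_len(nrow(conds))) {
    f <- conds$feature[i]
    if (!f %in% names(data)) {
      stop("rule references a feature absent from the cohort: ", f)
    }
    v <- data[[f]]
    ok <- ok & if (conds$op[i] == "<=") v <= conds$threshold[i]
               else v > conds$threshold[i]
  }
  ok
}

#' @export
print.subtype_rule <- function(x, ...) {
  cat(sprintf("<subtype_rule> %s (%s), %d unique members, gini %.3f\n",
              x$name %||% "?", x$category, length(x$member_ids), x$gini))
  for (i in seq_len(nrow(x$conditions))) {
    cat(sprintf("  %s %s %g\n", x$conditions$feature[i],
                x$conditions$op[i], x$conditions$threshold[i]))
  }
  invisible(x)
}

#' Apply a subtype rule to a cohort table
#'
#' A patient matches when every condition is satisfied (a conjunction).
#' The table must be imputed: missing values among rule features are not
#' allowed to silently fail conditions.
#'
#' @param rule a `subtype_rule` (or anything with a `conditions` tibble)
#' @param data a data frame with a `patient_id` column
#' @return character vector of matched patient ids
#' @export
apply_rule <- function(rule, data) {
  data$patient_id[apply_rule_matrix(rule$conditions, data)]
}

#' Criteria 1: minimum unique-patient size
#'
#' @param rule a `subtype_rule`
#' @param min_unique required number of unique member patients (default 10)
#' @return list with `n_unique` and `pass`
#' @export
criteria1_size <- function(rule, min_unique = 10L) {
  n <- length(unique(rule$member_ids))
  list(n_unique = n, pass = n >= min_unique)
}

#' Oversampling-adjusted minimum leaf row count
#'
#' With a majority:minority imbalance of `n_major:n_minor` after minority
#' oversampling, `base` unique minority patients correspond to about
#' `n_major / n_minor * base` rows; the ceiling of that is the row
#' threshold to enforce on minority-dominated leaves.
#'
#' @param n_major unique majority-class training patients
#' @param n_minor unique minority-class training patients
#' @param base required unique patients (default 10)
#' @return list with `raw` (real-valued) and `ceiling` (enforced rows)
#' @export
oversampled_min_leaf <- function(n_major, n_minor, base = 10) {
  stopifnot(n_minor > 0)
  raw <- n_major / n_minor * base
  list(raw = raw, ceiling = as.integer(ceiling(raw)))
}

#' Criteria-2 match threshold for a category
#'
#' The minimum external matches: the ceiling of `fraction` times the size
#' of the external class the category is validated against (early -> the
#' external early onset class, late -> late onset, mixed -> the whole
#' cohort).
#'
#' Mixed candidates are matched against every external patient, including
#' those excluded from labeling (boundary or juvenile onset), so `n_total`
#' can exceed `n_eopd + n_lopd`.
#'
#' @param category `"early"`, `"late"` or `"mixed"`
#' @param n_eopd,n_lopd external class sizes
#' @param n_total full external cohort size (defaults to the two classes)
#' @param fraction match fraction (default 0.05)
#' @return integer threshold
#' @export
criteria2_threshold <- function(category, n_eopd, n_lopd,
                                n_total = n_eopd + n_lopd, fraction = 0.05) {
  base <- switch(category, early = n_eopd, late = n_lopd, mixed = n_total,
                 stop("unknown category: ", category))
  as.integer(ceiling(fraction * base))
}

#' Criteria 2: sufficient external matches
#'
#' Early (late) candidates are matched against the external early (late)
#' onset patients only; mixed candidates against the full external cohort,
#' including patients excluded from labeling (`label` `NA`).
#'
#' @param rule a `subtype_rule`
#' @param external imputed external data frame with a `label` column of
#'   0/1 (`NA` for patients excluded from labeling)
#' @param fraction match fraction (default 0.05)
#' @return list with matched counts per class, the threshold and `pass`
#' @export
criteria2_external <- function(rule, external, fraction = 0.05) {
  if (nrow(external) == 0L) stop("external cohort is empty")
  matched <- external[apply_rule_matrix(rule$conditions, external), ,
                      drop = FALSE]
  m_e <- sum(matched$label == 0L, na.rm = TRUE)
  m_l <- sum(matched$label == 1L, na.rm = TRUE)
  n_e <- sum(external$label == 0L, na.rm = TRUE)
  n_l <- sum(external$label == 1L, na.rm = TRUE)
  thr <- criteria2_threshold(rule$category, n_e, n_l, nrow(external),
                             fraction)
  relevant <- switch(rule$category, early = m_e, late = m_l,
                     mixed = nrow(matched))
  list(matched_eopd = m_e, matched_lopd = m_l,
       matched_total = nrow(matched),
       n_eopd = n_e, n_lopd = n_l, n_total = nrow(external),
       threshold = thr, matches = relevant, pass = relevant >= thr)
}

#' Precision of a subtype on the external cohort
#'
#' Own-class matches over all matches.
#'
#' @param tp matches of the rule's own onset class
#' @param fp matches of the other onset class
#' @return precision, or `NA` when there are no matches
#' @export
subtype_precision <- function(tp, fp) {
  if (tp + fp == 0) return(NA_real_)
  tp / (tp + fp)
}

#' Criteria 3: precision above the external class prior
#'
#' Applicable to early and late candidates only; the threshold is the
#' external prior of the candidate's own class, and the precision must
#' strictly exceed it. Mixed candidates are exempt.
#'
#' @param category rule category
#' @param matched_eopd,matched_lopd external match counts by class
#' @param n_eopd,n_lopd external class sizes
#' @return list with `precision`, `threshold`, `applicable`, `pass`
#' @export
criteria3_precision <- function(category, matched_eopd, matched_lopd,
                                n_eopd, n_lopd) {
  if (category == "mixed") {
    return(list(precision = NA_real_, threshold = NA_real_,
                applicable = FALSE, pass = TRUE))
  }
  tp <- if (category == "early") matched_eopd else matched_lopd
  fp <- if (category == "early") matched_lopd else matched_eopd
  own <- if (category == "early") n_eopd else n_lopd
  prec <- subtype_precision(tp, fp)
  thr <- own / (n_eopd + n_lopd)
  if (is.na(prec)) {
    return(list(precision = NA_real_, threshold = thr, applicable = TRUE,
                pass = FALSE, reason = "no external matches"))
  }
  list(precision = prec, threshold = thr, applicable = TRUE,
       pass = prec > thr)
}

#' Run the three-criteria filter over candidate subtypes
#'
#' Applies the size, external-match and precision criteria in order and
#' reports every intermediate quantity, mirroring the published
#' selection/precision tables.
#'
#' @param rules list of `subtype_rule` objects
#' @param external imputed, labeled external data frame
#' @param min_unique Criteria-1 threshold (default 10)
#' @param fraction Criteria-2 match fraction (default 0.05)
#' @return list with `report` (one row per candidate) and `survivors`
#'   (names of rules passing all applicable criteria)
#' @export
run_filter_pipeline <- function(rules, external, min_unique = 10L,
                                fraction = 0.05) {
  rows <- lapply(rules, function(rule) {
    c1 <- criteria1_size(rule, min_unique)
    c2 <- criteria2_external(rule, external, fraction)
    c3 <- criteria3_precision(rule$category, c2$matched_eopd,
                              c2$matched_lopd, c2$n_eopd, c2$n_lopd)
    tibble::tibble(
      name = rule$name, category = rule$category, depth = rule$depth,
      n_unique = c1$n_unique, c1_pass = c1$pass,
      matched_eopd = c2$matched_eopd, matched_lopd = c2$matched_lopd,
      matched_total = c2$matched_total,
      c2_threshold = c2$threshold, c2_matches = c2$matches,
      c2_pass = c2$pass,
      precision = c3$precision, c3_threshold = c3$threshold,
      c3_applicable = c3$applicable, c3_pass = c3$pass,
      final_pass = c1$pass && c2$pass && c3$pass
    )
  })
  report <- do.call(rbind, rows)
  list(report = report, survivors = report$name[report$final_pass])
}

#' Replay the criteria 2-3 filter from printed match counts
#'
#' Runs the same threshold and precision logic as
#' [run_filter_pipeline()], but starting from already-tabulated external
#' match counts instead of rule evaluation — the form in which published
#' validation results are reported.
#'
#' @param counts data frame with columns `name`, `category`,
#'   `matched_eopd`, `matched_lopd` (either may be `NA` for mixed rows),
#'   `matched_total`
#' @param n_eopd,n_lopd external class sizes
#' @param n_total full external cohort size (defaults to the two classes)
#' @param fraction Criteria-2 match fraction (default 0.05)
#' @return list with `report` and `survivors`, as in
#'   [run_filter_pipeline()]
#' @export
filter_from_counts <- function(counts, n_eopd, n_lopd,
                               n_total = n_eopd + n_lopd, fraction = 0.05) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    thr <- criteria2_threshold(r$category, n_eopd, n_lopd, n_total, fraction)
    matches <- switch(r$category,
                      early = r$matched_eopd, late = r$matched_lopd,
                      mixed = r$matched_total)
    c2_pass <- matches >= thr
    c3 <- criteria3_precision(r$category,
                              r$matched_eopd %||% NA_integer_,
                              r$matched_lopd %||% NA_integer_,
                              n_eopd, n_lopd)
    tibble::tibble(
      name = r$name, category = r$category,
      matched_eopd = r$matched_eopd, matched_lopd = r$matched_lopd,
      matched_total = r$matched_total,
      c2_threshold = thr, c2_matches = matches, c2_pass = c2_pass,
      precision = c3$precision, c3_threshold = c3$threshold,
      c3_applicable = c3$applicable, c3_pass = c3$pass,
      final_pass = c2_pass && c3$pass
    )
  })
  report <- do.call(rbind, rows)
  list(report = report, survivors = report$name[report$final_pass])
}
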