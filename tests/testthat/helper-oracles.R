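# Independent oracles used against the package's own implementations.

# Exhaustive best-split search: every feature, every midpoint between
# consecutive distinct sorted values, impurity decrease computed from first
# principles. Ties resolve as the implementation promises: lowest feature
# index, then smallest threshold.
oracle_best_split <- function(x, y, min_leaf) {
  n <- length(y)
  gini <- function(yy) {
    p <- mean(yy == 1)
    1 - p^2 - (1 - p)^2
  }
  parent <- gini(y)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    vals <- sort(unique(x[, j]))
    if (length(vals) < 2L) next
    for (t in (vals[-length(vals)] + vals[-1]) / 2) {
      left <- x[, j] <= t
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      dec <- parent - mean(left) * gini(y[left]) -
        mean(!left) * gini(y[!left])
      if (dec > 1e-12 && (is.null(best) || dec > best$decrease + 1e-12)) {
        best <- list(feature = j, threshold = t, decrease = dec)
      }
    }
  }
  best
}

# AUROC by explicit pair counting: wins plus half-ties over all
# (positive, negative) pairs.
oracle_auroc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Rand index by explicit enumeration of all pairs.
oracle_rand <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      agree <- agree + (same_a == same_b)
    }
  }
  agree / choose(n, 2)
}

# A small hand-buildable cohort: n patients, a few ordinal items, complete
# ages. Values supplied explicitly so tests control every cell.
make_toy_cohort <- function(data) {
  feats <- setdiff(names(data), c("patient_id", "ageonset",
                                  "assessment_age", "gender"))
  dict <- tibble::tibble(
    feature = c("ageonset", "assessment_age", "gender", feats),
    kind = c("numeric", "numeric", "binary", rep("ordinal0_4", length(feats))),
    min = 0,
    max = c(120, 120, 1, rep(4, length(feats))),
    missingness = 0
  )
  pd_cohort(tibble::as_tibble(data), dict)
}

# Evaluate a planted rule by brute force against the raw generated table.
brute_rule_matches <- function(conditions, data) {
  ok <- rep(TRUE, nrow(data))
  for (i in seq_len(nrow(conditions))) {
    v <- data[[conditions$feature[i]]]
    ok <- ok & !is.na(v) &
      if (conditions$op[i] == "<=") v <= conditions$threshold[i]
      else v > conditions$threshold[i]
  }
  data$patient_id[ok]
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
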