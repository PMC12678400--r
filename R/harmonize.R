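# Cross-cohort feature harmonization.
#
# Subtype rules are learned on one cohort's variable names and evaluated on
# another's, so the two schemas must be reconciled first. A feature map lists
# exact name-for-name matches plus a handful of derived features (e.g. PD
# duration as assessment age minus onset age) whose values are computed
# row-wise from an arithmetic expression.

#' Load a feature map
#'
#' Reads a tab-separated file with columns `source`, `target`, `kind`
#' (`exact` or `derived`) and `derivation` (an arithmetic expression, only
#' for derived entries). Name matching is case-sensitive after trimming
#' whitespace.
#'
#' @param path TSV path
#' @param on_duplicate `"error"` rejects duplicated source names;
#'   `"first"` keeps the first occurrence and warns (clinical dictionaries
#'   occasionally list the same source under two target codes)
#' @return a tibble of class `feature_map` with one row per entry
#' @export
load_feature_map <- function(path, on_duplicate = c("error", "first")) {
  on_duplicate <- match.arg(on_duplicate)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), comment.char = "#")
  needed <- c("source", "target", "kind")
  if (!all(needed %in% names(raw))) {
    stop("feature map must have columns source, target, kind")
  }
  if (!"derivation" %in% names(raw)) raw$derivation <- NA_character_
  for (col in c("source", "target", "kind")) raw[[col]] <- trimws(raw[[col]])
  bad <- which(is.na(raw$source) | is.na(raw$target) |
                 !(raw$kind %in% c("exact", "derived")) |
                 (raw$kind == "derived" & is.na(raw$derivation)))
  if (length(bad) > 0L) {
    stop("malformed feature-map row at line ", bad[1] + 1L,
         " (counting the header as line 1)")
  }
  dup <- duplicated(raw$source)
  if (any(dup)) {
    if (on_duplicate == "error") {
      stop("duplicated source feature(s) in map: ",
           paste(unique(raw$source[dup]), collapse = ", "))
    }
    warning("keeping first occurrence of duplicated source feature(s): ",
            paste(unique(raw$source[dup]), collapse = ", "))
    raw <- raw[!dup, ]
  }
  out <- tibble::as_tibble(raw[, c("source", "target", "kind", "derivation")])
  class(out) <- c("feature_map", class(out))
  out
}

#' Write a feature map to TSV
#' @param map a `feature_map`
#' @param path output path
#' @export
write_feature_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' The packaged training/validation feature map
#'
#' The mapping between the LRRK2-style training schema and the MDS-style
#' validation schema: exact one-to-one name matches for the MDS-UPDRS items
#' and demographics, plus the derived entries (PD duration, Epworth score).
#'
#' @param on_duplicate passed to [load_feature_map()]; the shipped map lists
#'   the Hoehn & Yahr stage under two validation codes, so the default keeps
#'   the first occurrence
#' @return a `feature_map`
#' @export
lrrk2_mds_feature_map <- function(on_duplicate = "first") {
  path <- system.file("extdata", "lrrk2_mds_feature_map.tsv",
                      package = "onsettree", mustWork = TRUE)
  suppressWarnings(load_feature_map(path, on_duplicate = on_duplicate))
}

# Evaluate a derivation expression row-wise over the columns of `data` only;
# anything but arithmetic on known columns is rejected.
eval_derivation <- function(expr_text, data) {
  expr <- tryCatch(str2lang(expr_text),
                   error = function(e) stop("unparsable derivation: ", expr_text))
  vars <- all.vars(expr)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0L) {
    stop("derivation references feature(s) absent from the cohort: ",
         paste(missing_vars, collapse = ", "))
  }
  allowed_fns <- c("+", "-", "*", "/", "(", "pmin", "pmax")
  fns <- setdiff(all.names(expr), vars)
  if (!all(fns %in% allowed_fns)) {
    stop("derivation uses disallowed function(s): ",
         paste(setdiff(fns, allowed_fns), collapse = ", "))
  }
  eval(expr, envir = data, enclos = baseenv())
}

#' Apply a feature map to a cohort
#'
#' Forward direction renames source-named columns to their target names;
#' reverse renames target-named columns back to source names. Derived
#' entries are one-way: the derivation is evaluated row-wise over the
#' columns of the cohort being transformed and emits the mapped name of the
#' requested direction; missing inputs propagate to a missing derived value,
#' and a derivation referencing a column absent from the cohort is an error.
#' Exact entries whose column is absent are skipped with a warning.
#' Unmapped columns are dropped from the harmonized view but preserved in
#' the `auxiliary` attribute.
#'
#' Derived entries are evaluated in the forward direction only (the reverse
#' of an arithmetic derivation is not defined); the core columns
#' (`patient_id`, ages, gender) are always carried through so the container
#' stays valid.
#'
#' @param cohort a `pd_cohort`
#' @param map a `feature_map`
#' @param direction `"forward"` (source -> target) or `"reverse"`
#' @param missing_inputs what to do with a derived entry whose derivation
#'   references a column absent from the cohort: `"error"` (default) or
#'   `"skip"` with a warning — useful for maps that bundle derivations
#'   oriented toward the other schema
#' @return a `pd_cohort` whose clinical columns carry the mapped names; the
#'   dropped unmapped columns are in `attr(, "auxiliary")`
#' @export
apply_feature_map <- function(cohort, map, direction = c("forward", "reverse"),
                              missing_inputs = c("error", "skip")) {
  direction <- match.arg(direction)
  missing_inputs <- match.arg(missing_inputs)
  data <- cohort$data
  from <- if (direction == "forward") map$source else map$target
  to <- if (direction == "forward") map$target else map$source
  core <- c("patient_id", "ageonset", "assessment_age", "gender")

  out <- data[, "patient_id", drop = FALSE]
  mapped_from <- character(0)
  for (i in seq_len(nrow(map))) {
    if (map$kind[i] == "exact") {
      if (!from[i] %in% names(data)) {
        warning("skipping map entry for absent feature: ", from[i])
        next
      }
      out[[to[i]]] <- data[[from[i]]]
      mapped_from <- c(mapped_from, from[i])
    } else {
      if (direction == "reverse") next  # derived entries are one-way
      inputs <- all.vars(str2lang(map$derivation[i]))
      if (!all(inputs %in% names(data)) && missing_inputs == "skip") {
        warning("skipping derived entry ", map$target[i],
                ": input(s) absent: ",
                paste(setdiff(inputs, names(data)), collapse = ", "))
        next
      }
      out[[to[i]]] <- eval_derivation(map$derivation[i], data)
    }
  }
  for (col in setdiff(core, names(out))) {
    if (col %in% names(data)) out[[col]] <- data[[col]]
  }
  aux_cols <- setdiff(names(data), c(core, mapped_from))
  aux <- data[, c("patient_id", aux_cols), drop = FALSE]

  old_dict <- cohort$dictionary
  ren <- stats::setNames(to, from)
  dict_feat <- names(out)[-1]
  orig <- names(ren)[match(dict_feat, ren)]
  lookup <- ifelse(is.na(orig), dict_feat, orig)
  idx <- match(lookup, old_dict$feature)
  dictionary <- tibble::tibble(
    feature = dict_feat,
    kind = ifelse(is.na(idx), "numeric", old_dict$kind[idx]),
    min = ifelse(is.na(idx), -Inf, old_dict$min[idx]),
    max = ifelse(is.na(idx), Inf, old_dict$max[idx]),
    missingness = ifelse(is.na(idx), 0, old_dict$missingness[idx])
  )
  res <- pd_cohort(out, dictionary)
  res$planted <- cohort$planted
  attr(res, "auxiliary") <- aux
  res
}
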