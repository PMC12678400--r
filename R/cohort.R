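#' Patient cohort container
#'
#' A `pd_cohort` bundles a patient table with its data dictionary. The table
#' always starts with the columns `patient_id`, `ageonset`, `assessment_age`,
#' `gender`, followed by the clinical items; the dictionary records, for every
#' non-id column, its kind (`ordinal0_4`, `integer0_15`, `binary`, `numeric`),
#' admissible range and the configured missingness rate.
#'
#' @param data a data frame with the fixed leading columns described above
#' @param dictionary a data frame with columns `feature`, `kind`, `min`,
#'   `max`, `missingness`
#' @return an object of class `pd_cohort`
#' @export
pd_cohort <- function(data, dictionary) {
  data <- tibble::as_tibble(data)
  dictionary <- tibble::as_tibble(dictionary)
  core <- c("patient_id", "ageonset", "assessment_age", "gender")
  if (!all(core %in% names(data))) {
    stop("cohort table must contain columns: ", paste(core, collapse = ", "))
  }
  needed <- c("feature", "kind", "min", "max", "missingness")
  if (!all(needed %in% names(dictionary))) {
    stop("dictionary must contain columns: ", paste(needed, collapse = ", "))
  }
  extra <- setdiff(setdiff(names(data), "patient_id"), dictionary$feature)
  if (length(extra) > 0L) {
    stop("columns missing from dictionary: ", paste(extra, collapse = ", "))
  }
  data <- data[, c(core, setdiff(names(data), core))]
  structure(list(data = data, dictionary = dictionary), class = "pd_cohort")
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat(sprintf(
    "<pd_cohort> %d patients, %d clinical features\n",
    nrow(x$data), ncol(x$data) - 4L
  ))
  invisible(x)
}

#' Clinical feature names of a cohort
#'
#' Everything after the four leading core columns.
#'
#' @param cohort a `pd_cohort`
#' @return character vector of feature names
#' @export
clinical_features <- function(cohort) {
  setdiff(names(cohort$data), c("patient_id", "ageonset", "assessment_age"))
}

#' Write a cohort as CSV plus a sidecar JSON data dictionary
#'
#' @param cohort a `pd_cohort`
#' @param csv_path output CSV path
#' @param dict_path output JSON path; defaults to the CSV path with a
#'   `_dict.json` suffix
#' @return invisibly, the two paths
#' @export
write_cohort <- function(cohort, csv_path, dict_path = NULL) {
  dict_path <- dict_path %||% sub("\\.csv$", "_dict.json", csv_path)
  utils::write.csv(cohort$data, csv_path, row.names = FALSE, na = "")
  dict <- cohort$dictionary
  dict$pct_missing <- vapply(
    dict$feature,
    function(f) round(100 * mean(is.na(cohort$data[[f]])), 2),
    numeric(1)
  )
  jsonlite::write_json(dict, dict_path, dataframe = "rows", na = "null")
  invisible(c(csv_path, dict_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param csv_path CSV path
#' @param dict_path JSON dictionary path (same default convention as
#'   [write_cohort()])
#' @return a `pd_cohort`
#' @export
read_cohort <- function(csv_path, dict_path = NULL) {
  dict_path <- dict_path %||% sub("\\.csv$", "_dict.json", csv_path)
  data <- utils::read.csv(csv_path, colClasses = c(patient_id = "character"),
                          na.strings = c("NA", ""))
  dict <- jsonlite::fromJSON(dict_path)
  dict$pct_missing <- NULL
  pd_cohort(data, dict)
}
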