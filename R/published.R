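# Published reference numbers from the LRRK2/MDS subtyping study that this
# pipeline emulates. These printed tables are inputs: the training data
# behind them are access-controlled, but the filtering and characterization
# arithmetic can be replayed through the package's own functions, which is
# exactly what the acceptance checks do.

#' External class sizes and training imbalance of the reference study
#'
#' The validation cohort held 402 patients, of whom 321 were late onset and
#' 68 early onset after exclusions; the training split held 197 late onset
#' and 107 early onset unique patients.
#'
#' @return named list: `n_eopd`, `n_lopd`, `n_total`, `train_majority`,
#'   `train_minority`
#' @export
reference_class_sizes <- function() {
  list(n_eopd = 68L, n_lopd = 321L, n_total = 402L,
       train_majority = 197L, train_minority = 107L)
}

#' Published external-validation match counts per candidate subtype
#'
#' One row per candidate subtype with at least one external match: the
#' onset category, the matches in the candidate's own class
#' (`matched_eopd`/`matched_lopd` for early/late candidates; mixed
#' candidates report only a total against the full cohort), and the
#' published match percentages.
#'
#' @return tibble with columns `name`, `category`, `depth`,
#'   `matched_eopd`, `matched_lopd`, `matched_total`, `tp_pct`, `fp_pct`
#' @export
reference_validation_counts <- function() {
  tab <- tibble::tribble(
    ~name, ~category, ~depth, ~matched_eopd, ~matched_lopd, ~tp_pct, ~fp_pct,
    "E1", "early", 3L,  2L,  9L,  2.9, 2.8,
    "E2", "early", 4L,  3L, 23L,  4.4, 7.2,
    "E3", "early", 3L,  3L,  5L,  4.4, 1.6,
    "E4", "early", 4L, 20L, 50L, 29.4, 15.6,
    "L1", "late",  6L,  6L, 39L, 12.2, 8.8,
    "L2", "late",  5L,  1L, 29L,  9.0, 1.5,
    "L3", "late",  3L,  0L,  7L,  2.2, 0.0,
    "L4", "late",  5L,  4L, 25L,  7.8, 5.9,
    "L5", "late",  5L,  0L,  7L,  2.2, 0.0,
    "L6", "late",  7L,  2L, 12L,  3.7, 2.9,
    "M1", "mixed", 5L,  NA,  NA,  2.0, NA,
    "M2", "mixed", 3L,  NA,  NA,  0.5, NA,
    "M3", "mixed", 5L,  NA,  NA, 11.7, NA,
    "M4", "mixed", 6L,  NA,  NA,  0.5, NA,
    "M5", "mixed", 8L,  NA,  NA,  1.2, NA,
    "M6", "mixed", 4L,  NA,  NA,  4.0, NA,
    "M7", "mixed", 3L,  NA,  NA,  9.5, NA
  )
  mixed_totals <- c(M1 = 8L, M2 = 2L, M3 = 47L, M4 = 2L, M5 = 5L,
                    M6 = 16L, M7 = 38L)
  tab$matched_total <- ifelse(
    tab$category == "mixed",
    mixed_totals[tab$name],
    tab$matched_eopd + tab$matched_lopd
  )
  tab
}

#' Published precision table for the early/late finalists
#'
#' @return tibble with `name`, `matched_eopd`, `matched_lopd`,
#'   `precision`, `threshold` as published
#' @export
reference_precision_table <- function() {
  tibble::tribble(
    ~name, ~matched_eopd, ~matched_lopd, ~precision, ~threshold,
    "E4", 20L, 50L, 0.286, 0.175,
    "L1",  6L, 39L, 0.867, 0.825,
    "L2",  1L, 29L, 0.967, 0.825,
    "L4",  4L, 25L, 0.862, 0.825
  )
}

#' Published subtype characteristics (training cohort)
#'
#' Patient counts, assessment-age and onset-age summaries, and the binary
#' diagnostic check-sheet ratios for the six final subtypes and the overall
#' cohort, as published. Check-sheet values are positive-score ratios.
#'
#' @return list with `demographics` (tibble: one row per subtype plus
#'   `Overall`) and `checksheet` (tibble: one row per feature, one column
#'   per subtype plus `Overall`)
#' @export
reference_subtype_profile <- function() {
  demographics <- tibble::tribble(
    ~subtype, ~n, ~assessment_age_mean, ~assessment_age_sd,
    ~ageonset_mean, ~ageonset_sd, ~n_male, ~n_female,
    "E4", 27L, 49.44, 10.46, 42.63, 10.48, 13L, 14L,
    "M3", 26L, 60.50, 10.38, 52.77, 12.17, 17L,  9L,
    "M7", 25L, 63.04, 10.74, 51.44, 13.29, 18L,  7L,
    "L1", 21L, 65.29,  9.37, 60.86,  8.58, 13L,  8L,
    "L2", 25L, 64.40,  9.98, 58.60, 10.28, 11L, 14L,
    "L4", 27L, 66.78,  9.80, 57.89, 10.94, 15L, 12L,
    "Overall", 397L, 62.53, 12.06, 54.50, 12.97, 214L, 183L
  )
  checksheet <- tibble::tribble(
    ~feature, ~E4, ~M3, ~M7, ~L1, ~L2, ~L4, ~Overall,
    "DCBRADY",  1.0,   1.0,   1.0,  1.0,   1.0,  1.0,   0.997,
    "DCRIGID",  0.852, 0.769, 0.96, 0.905, 0.84, 0.926, 0.856,
    "DCRTREM",  0.556, 0.846, 0.88, 0.857, 0.76, 0.852, 0.826,
    "MPTPEXP",  0.0,   0.0,   0.0,  0.0,   0.0,  0.037, 0.003,
    "BABINSKI", 0.0,   0.0,   0.0,  0.0,   0.0,  0.037, 0.005,
    "NELEONSX", 0.0,   0.0,   0.0,  0.0,   0.0,  0.074, 0.010,
    "AUNOERLY", 0.0,   0.077, 0.0,  0.0,   0.0,  0.074, 0.018,
    "RTRMHZ",   0.704, 1.0,   1.0,  1.0,   0.88, 1.0,   0.937,
    "DCPRGDIS", 0.889, 1.0,   1.0,  0.952, 1.0,  1.0,   0.972,
    "DCASYMM",  0.556, 0.808, 0.88, 0.524, 0.56, 0.704, 0.698,
    "DCLDOPCH", 0.0,   0.038, 0.12, 0.0,   0.0,  0.037, 0.045,
    "DCPD10Y",  0.185, 0.269, 0.48, 0.095, 0.12, 0.296, 0.239,
    "HXENCEPH", 0.0,   0.0,   0.0,  0.0,   0.0,  0.037, 0.003,
    "DCPOSINS", 0.148, 0.115, 0.44, 0.048, 0.16, 0.148, 0.232,
    "STRKSTPD", 0.0,   0.0,   0.0,  0.0,   0.0,  0.037, 0.005,
    "SUSTRMS",  0.0,   0.0,   0.0,  0.0,   0.0,  0.074, 0.005,
    "OGC",      0.0,   0.0,   0.0,  0.0,   0.0,  0.037, 0.003,
    "SGPSVSAC", 0.0,   0.0,   0.0,  0.0,   0.0,  0.074, 0.008,
    "CERESIGN", 0.0,   0.0,   0.0,  0.0,   0.0,  0.037, 0.003,
    "HXUNIL3Y", 0.0,   0.077, 0.0,  0.0,   0.0,  0.037, 0.018
  )
  list(demographics = demographics, checksheet = checksheet)
}
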