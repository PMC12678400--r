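# Synthetic paired-cohort generator.
#
# The generator stands in for the access-controlled clinical datasets: it
# emulates their statistical shape (ordinal 0-4 rating items, a 0-15
# depression score, gender, a ~2:1 late:early onset imbalance, per-feature
# missingness, a validation cohort shifted older) and plants conjunction-of-
# conditions subtypes correlated with onset class so the downstream rule
# recovery machinery can be tested against a known ground truth. Every
# distributional choice here is a stand-in, not an estimate from real data.

#' Declare a planted subtype
#'
#' A planted subtype is a ground-truth rule: a conjunction of
#' (feature, operator, threshold) conditions, a prevalence, an onset-class
#' skew and an adherence probability. Members are drawn first; with
#' probability `adherence` a member's condition features are redrawn from the
#' baseline distribution truncated to the satisfying range, so the member
#' matches every condition.
#'
#' @param conditions data frame with columns `feature`, `op` (one of
#'   `"<="`, `">"`), `threshold`
#' @param prevalence fraction of the cohort belonging to the subtype
#' @param onset_skew fraction of members assigned the late onset class
#' @param adherence probability in (0.5, 1] that a member is forced to
#'   satisfy every condition
#' @return a `planted_subtype` object
#' @export
planted_subtype <- function(conditions, prevalence, onset_skew, adherence = 1) {
  conditions <- tibble::as_tibble(conditions)
  stopifnot(
    all(c("feature", "op", "threshold") %in% names(conditions)),
    all(conditions$op %in% c("<=", ">")),
    prevalence > 0, prevalence < 1,
    onset_skew >= 0, onset_skew <= 1,
    adherence > 0.5, adherence <= 1
  )
  structure(
    list(conditions = conditions, prevalence = prevalence,
         onset_skew = onset_skew, adherence = adherence),
    class = "planted_subtype"
  )
}

#' Default clinical feature schema
#'
#' Seventy ordinal 0-4 rating items organised like the four parts of the
#' MDS-UPDRS (13 non-motor, 13 motor experiences of daily living, 38 motor
#' examination, 6 motor complication items), a 0-15 geriatric depression
#' score, and binary gender. Baseline ordinal distributions are truncated
#' geometric with mass concentrated on 0-1, mirroring the predominance of
#' Normal/Slight ratings in mildly affected cohorts and keeping background
#' rule-match rates low.
#'
#' @param ordinal_decay geometric decay of the ordinal baseline; category k
#'   has mass proportional to `ordinal_decay^k`
#' @param gds_decay geometric decay of the 0-15 depression score
#' @param p_male baseline probability of gender code 1
#' @return a tibble with columns `name`, `kind`, `probs` (list column)
#' @export
default_feature_schema <- function(ordinal_decay = 0.45, gds_decay = 0.75,
                                   p_male = 0.54) {
  parts <- c(updrs1 = 13L, updrs2 = 13L, updrs3 = 38L, updrs4 = 6L)
  nm <- unlist(lapply(names(parts), function(p) {
    sprintf("%s_%02d", p, seq_len(parts[[p]]))
  }))
  ord_probs <- ordinal_decay^(0:4)
  ord_probs <- ord_probs / sum(ord_probs)
  gds_probs <- gds_decay^(0:15)
  gds_probs <- gds_probs / sum(gds_probs)
  tibble::tibble(
    name = c("gender", nm, "gds15_score"),
    kind = c("binary", rep("ordinal0_4", length(nm)), "integer0_15"),
    probs = c(list(c(1 - p_male, p_male)),
              rep(list(ord_probs), length(nm)),
              list(gds_probs))
  )
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate
#' the study conditions: a ~2:1 late:early onset mix, early onset ages
#' centred on 42.6 years and late onset on 58 years (sd 10.5, truncated to
#' the class ranges and rounded to whole years), a disease-duration offset
#' of about 8 years between onset and assessment, low per-feature
#' missingness with a few noisier items, a validation cohort shifted 5 years
#' older, and two planted subtypes (one late-skewed, one early-skewed).
#'
#' @param n_patients cohort size
#' @param onset_mix background fraction of late onset patients
#' @param onset_age_params list with elements `eopd` and `lopd`, each
#'   `c(mean, sd)` in years
#' @param assessment_offset_params `c(mean, sd)` of assessment age minus
#'   onset age, years, truncated at zero
#' @param feature_schema see [default_feature_schema()]
#' @param planted_subtypes list of [planted_subtype()] objects
#' @param missingness single rate or named vector of per-feature missing
#'   fractions, each in [0, 0.3]
#' @param demographic_shift_years additive shift (years) applied to the
#'   validation cohort's onset (and hence assessment) ages
#' @param seed integer seed; expanded into independent per-cohort,
#'   per-stage substreams
#' @return a `generator_config` object
#' @export
generator_config <- function(n_patients = 400,
                             onset_mix = 2 / 3,
                             onset_age_params = list(
                               eopd = c(mean = 42.6, sd = 10.5),
                               lopd = c(mean = 58, sd = 10.5)
                             ),
                             assessment_offset_params = c(mean = 8, sd = 5),
                             feature_schema = default_feature_schema(),
                             planted_subtypes = default_planted_subtypes(),
                             missingness = 0.02,
                             demographic_shift_years = 5,
                             seed = 1L) {
  feature_schema <- tibble::as_tibble(feature_schema)
  stopifnot(
    n_patients >= 1,
    onset_mix > 0, onset_mix < 1,
    all(c("name", "kind", "probs") %in% names(feature_schema))
  )
  for (i in seq_len(nrow(feature_schema))) {
    p <- feature_schema$probs[[i]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("category probabilities of feature ", feature_schema$name[i],
           " must be nonnegative and sum to 1")
    }
  }
  if (length(missingness) == 1L && is.null(names(missingness))) {
    missingness <- stats::setNames(
      rep(missingness, nrow(feature_schema)), feature_schema$name
    )
    missingness["gender"] <- 0
  }
  miss <- stats::setNames(rep(0, nrow(feature_schema)), feature_schema$name)
  miss[names(missingness)] <- missingness
  if (any(miss < 0 | miss > 0.3)) {
    stop("per-feature missingness must lie in [0, 0.3]")
  }
  prev <- vapply(planted_subtypes, function(s) s$prevalence, numeric(1))
  if (sum(prev) > 1) stop("planted prevalences must sum to at most 1")
  cfg <- list(
    n_patients = as.integer(n_patients),
    onset_mix = onset_mix,
    onset_age_params = onset_age_params,
    assessment_offset_params = assessment_offset_params,
    feature_schema = feature_schema,
    planted_subtypes = planted_subtypes,
    missingness = miss,
    demographic_shift_years = demographic_shift_years,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_planted_rules(cfg)
  cfg
}

#' Default planted subtypes
#'
#' One late-skewed and one early-skewed conjunction of two rarely-satisfied
#' motor/non-motor conditions, 10% prevalence each. These are the ground
#' truth the recovery tests aim at; real cohorts have no such labels.
#'
#' @return list of two [planted_subtype()] objects
#' @export
default_planted_subtypes <- function() {
  list(
    planted_subtype(
      conditions = tibble::tibble(
        feature = c("updrs3_10", "updrs2_12"), op = c(">", ">"),
        threshold = c(2, 2)
      ),
      prevalence = 0.10, onset_skew = 0.9, adherence = 0.95
    ),
    planted_subtype(
      conditions = tibble::tibble(
        feature = c("updrs1_13", "updrs3_17"), op = c(">", ">"),
        threshold = c(2, 2)
      ),
      prevalence = 0.10, onset_skew = 0.1, adherence = 0.95
    )
  )
}

# Reject conditions that no category of the feature's baseline can satisfy.
validate_planted_rules <- function(config) {
  schema <- config$feature_schema
  for (s in config$planted_subtypes) {
    for (i in seq_len(nrow(s$conditions))) {
      cond <- s$conditions[i, ]
      j <- match(cond$feature, schema$name)
      if (is.na(j)) {
        stop("infeasible condition: feature ", cond$feature,
             " is not in the feature schema")
      }
      vals <- seq_along(schema$probs[[j]]) - 1
      ok <- if (cond$op == "<=") vals <= cond$threshold else vals > cond$threshold
      if (!any(ok & schema$probs[[j]] > 0)) {
        stop(sprintf("infeasible condition: %s %s %s has no satisfiable value",
                     cond$feature, cond$op, format(cond$threshold)))
      }
    }
  }
  invisible(config)
}

# Truncated-normal draw via inverse CDF, vectorised.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

round_half_up <- function(x) floor(x + 0.5)

# Draw n values from a categorical baseline, optionally truncated to the
# range satisfying one rule condition.
draw_categorical <- function(n, probs, op = NULL, threshold = NULL) {
  vals <- seq_along(probs) - 1
  if (!is.null(op)) {
    keep <- if (op == "<=") vals <= threshold else vals > threshold
    vals <- vals[keep]
    probs <- probs[keep]
  }
  if (length(vals) == 1L) return(rep(vals, n))
  sample(vals, n, replace = TRUE, prob = probs)
}

#' Generate one synthetic cohort
#'
#' Planted-subtype members are drawn first (by prevalence, as row blocks),
#' their onset class drawn from the subtype's `onset_skew`, and — with
#' probability `adherence` per member — their condition features redrawn so
#' the member satisfies every rule condition. Remaining patients draw all
#' features from the baseline distributions and their onset class from
#' `onset_mix`. Missingness is then injected independently per cell at the
#' configured per-feature rate (never on ages or patient ids). Ground-truth
#' membership is kept in the `planted` element of the result.
#'
#' @param config a [generator_config()]
#' @param id_prefix prefix of generated patient ids
#' @param shift_years additive demographic shift (years) applied to drawn
#'   onset ages; used by [generate_paired_cohorts()] for the validation arm
#' @return a `pd_cohort` with an extra `planted` element: one entry per
#'   planted subtype holding `conditions`, `member_ids` and `adhering_ids`
#' @export
generate_cohort <- function(config, id_prefix = "P", shift_years = 0) {
  stopifnot(inherits(config, "generator_config"))
  validate_planted_rules(config)
  n <- config$n_patients
  schema <- config$feature_schema
  ids <- sprintf("%s%05d", id_prefix, seq_len(n))

  # stage 1: planted membership as leading row blocks
  sizes <- vapply(config$planted_subtypes, function(s) {
    as.integer(round(s$prevalence * n))
  }, integer(1))
  if (sum(sizes) > n) stop("planted subtypes exceed the cohort size")
  membership <- rep(0L, n)
  at <- 0L
  for (k in seq_along(sizes)) {
    membership[at + seq_len(sizes[k])] <- k
    at <- at + sizes[k]
  }

  # stage 2: onset class (1 = late)
  set.seed(substream_seed(config$seed, 2L))
  skews <- vapply(config$planted_subtypes, function(s) s$onset_skew, numeric(1))
  p_late <- c(config$onset_mix, skews)[membership + 1L]
  late <- stats::rbinom(n, 1L, p_late)

  # stage 3: ages (years); onset truncated to the class range, then the
  # demographic shift, then a nonnegative disease-duration offset
  set.seed(substream_seed(config$seed, 3L))
  eo <- config$onset_age_params$eopd
  lo <- config$onset_age_params$lopd
  ao <- numeric(n)
  ao[late == 0L] <- rtruncnorm(sum(late == 0L), eo[["mean"]], eo[["sd"]],
                               21.5, 49.499)
  ao[late == 1L] <- rtruncnorm(sum(late == 1L), lo[["mean"]], lo[["sd"]],
                               50.5, 90)
  ao <- round_half_up(ao + shift_years)
  off <- config$assessment_offset_params
  offset <- rtruncnorm(n, off[["mean"]], off[["sd"]], 0, Inf)
  assessment <- round_half_up(ao + offset)

  # stage 4: clinical features from baseline, then per-subtype adherence
  # forcing (condition features redrawn from the truncated baseline)
  set.seed(substream_seed(config$seed, 4L))
  feat <- matrix(NA_real_, n, nrow(schema),
                 dimnames = list(NULL, schema$name))
  for (j in seq_len(nrow(schema))) {
    feat[, j] <- draw_categorical(n, schema$probs[[j]])
  }
  planted <- vector("list", length(config$planted_subtypes))
  for (k in seq_along(config$planted_subtypes)) {
    sub <- config$planted_subtypes[[k]]
    rows <- which(membership == k)
    adheres <- stats::rbinom(length(rows), 1L, sub$adherence) == 1L
    forced <- rows[adheres]
    for (i in seq_len(nrow(sub$conditions))) {
      cond <- sub$conditions[i, ]
      j <- match(cond$feature, schema$name)
      feat[forced, j] <- draw_categorical(
        length(forced), schema$probs[[j]], cond$op, cond$threshold
      )
    }
    planted[[k]] <- list(
      conditions = sub$conditions,
      member_ids = ids[rows],
      adhering_ids = ids[forced]
    )
  }

  # stage 5: missingness, independent per cell at the per-feature rate
  set.seed(substream_seed(config$seed, 5L))
  for (j in seq_len(nrow(schema))) {
    rate <- config$missingness[[schema$name[j]]]
    if (rate > 0) {
      feat[stats::runif(n) < rate, j] <- NA_real_
    }
  }

  data <- tibble::as_tibble(as.data.frame(feat))
  data <- tibble::add_column(
    data[, setdiff(names(data), "gender")],
    patient_id = ids, ageonset = as.numeric(ao),
    assessment_age = as.numeric(assessment),
    gender = data$gender, .before = 1
  )
  dictionary <- tibble::tibble(
    feature = c("ageonset", "assessment_age", schema$name),
    kind = c("numeric", "numeric", schema$kind),
    min = c(0, 0, vapply(schema$probs, function(p) 0, numeric(1))),
    max = c(120, 120, vapply(schema$probs, function(p) length(p) - 1,
                             numeric(1))),
    missingness = c(0, 0, unname(config$missingness[schema$name]))
  )
  cohort <- pd_cohort(data, dictionary)
  cohort$planted <- planted
  cohort
}

#' Generate a paired training/validation cohort
#'
#' Both cohorts share the feature schema and planted subtypes; the
#' validation cohort draws from independent substreams and has its onset
#' (and hence assessment) ages shifted older by
#' `config$demographic_shift_years`, emulating the demographic gap between
#' a mutation-enriched training cohort and a general validation cohort.
#'
#' @param config a [generator_config()]
#' @return list with elements `training` and `validation`, both `pd_cohort`
#' @export
generate_paired_cohorts <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg_t <- config
  cfg_t$seed <- substream_seed(config$seed, 101L)
  cfg_v <- config
  cfg_v$seed <- substream_seed(config$seed, 202L)
  list(
    training = generate_cohort(cfg_t, id_prefix = "T"),
    validation = generate_cohort(cfg_v, id_prefix = "V",
                                 shift_years = config$demographic_shift_years)
  )
}
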