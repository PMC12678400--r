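# Feature-map loading and application: exact renames, derived features,
# duplicate handling, round trips.

write_map <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("source\ttarget\tkind\tderivation", lines), path)
  path
}

test_that("the packaged map parses and contains the expected entries", {
  map <- lrrk2_mds_feature_map()
  gait <- map[map$source == "NP3GAIT", ]
  expect_equal(gait$target, "mdsupdrs3_10")
  expect_equal(gait$kind, "exact")
  # the Hoehn & Yahr stage is listed twice; only the first survives
  expect_equal(sum(map$source == "NHY"), 1L)
  expect_equal(map$target[map$source == "NHY"], "mdsupdrs_hy")
  path <- system.file("extdata", "lrrk2_mds_feature_map.tsv",
                      package = "onsettree")
  expect_error(load_feature_map(path, on_duplicate = "error"), "NHY")
})

test_that("empty and malformed maps are handled", {
  empty <- load_feature_map(write_map(character(0)))
  expect_equal(nrow(empty), 0L)
  expect_error(load_feature_map(write_map(c("a\tb\texact", "c\t\texact"))),
               "line 3")
  expect_error(
    load_feature_map(write_map(c("a\tb\texact", "a\tc\texact"))),
    "duplicated"
  )
})

toy <- function() {
  make_toy_cohort(tibble::tibble(
    patient_id = c("P1", "P2"),
    ageonset = c(59, 40), assessment_age = c(67, 45),
    gender = c(1, 0), itemA = c(3, 1), itemB = c(0, 2)
  ))
}

test_that("an identity map leaves mapped columns unchanged", {
  map <- load_feature_map(write_map(c("itemA\titemA\texact",
                                      "itemB\titemB\texact")))
  out <- apply_feature_map(toy(), map)
  expect_equal(out$data$itemA, c(3, 1))
  expect_equal(out$data$itemB, c(0, 2))
})

test_that("derived disease duration is assessment age minus onset age", {
  map <- load_feature_map(write_map(c(
    "itemA\tmds_A\texact",
    "pd_duration\tdurat_pd\tderived\tassessment_age - ageonset"
  )))
  out <- apply_feature_map(toy(), map)
  expect_equal(out$data$durat_pd, c(8, 5))
  # exact entries are renamed, never altered
  expect_equal(out$data$mds_A, c(3, 1))
})

test_that("derived entries propagate missing inputs and error on absent ones", {
  cohort <- toy()
  cohort$data$itemA[1] <- NA
  map <- load_feature_map(write_map(
    "x\tsum_item\tderived\titemA + itemB"
  ))
  out <- apply_feature_map(cohort, map)
  expect_true(is.na(out$data$sum_item[1]))
  expect_equal(out$data$sum_item[2], 3)
  bad <- load_feature_map(write_map("x\ty\tderived\tghost + itemB"))
  expect_error(apply_feature_map(toy(), bad), "ghost")
  expect_warning(
    out2 <- apply_feature_map(toy(), bad, missing_inputs = "skip"), "ghost"
  )
  expect_false("y" %in% names(out2$data))
})

test_that("forward then reverse restores exact names and values", {
  map <- load_feature_map(write_map(c("itemA\tmds_A\texact",
                                      "itemB\tmds_B\texact")))
  fwd <- apply_feature_map(toy(), map, "forward")
  expect_setequal(setdiff(names(fwd$data),
                          c("patient_id", "ageonset", "assessment_age",
                            "gender")),
                  c("mds_A", "mds_B"))
  back <- apply_feature_map(fwd, map, "reverse")
  expect_equal(back$data$itemA, c(3, 1))
  expect_equal(back$data$itemB, c(0, 2))
})

test_that("absent exact sources are skipped with a warning", {
  map <- load_feature_map(write_map(c("itemA\tmds_A\texact",
                                      "missing_item\tmds_X\texact")))
  expect_warning(out <- apply_feature_map(toy(), map), "missing_item")
  expect_false("mds_X" %in% names(out$data))
})

test_that("a full-schema map yields cohorts sharing exactly its columns", {
  cfg <- generator_config(n_patients = 40, missingness = 0, seed = 2)
  pair <- generate_paired_cohorts(cfg)
  feats <- setdiff(names(pair$training$data),
                   c("patient_id", "ageonset", "assessment_age", "gender"))
  map <- load_feature_map(write_map(
    sprintf("%s\tv_%s\texact", feats, feats)
  ))
  ht <- apply_feature_map(pair$training, map)
  hv <- apply_feature_map(pair$validation, map)
  shared <- intersect(
    setdiff(names(ht$data),
            c("patient_id", "ageonset", "assessment_age", "gender")),
    setdiff(names(hv$data),
            c("patient_id", "ageonset", "assessment_age", "gender"))
  )
  expect_length(shared, length(feats))
  expect_true(all(startsWith(shared, "v_")))
})
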