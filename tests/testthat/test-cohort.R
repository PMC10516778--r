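# Cohort container: CSV round-trips, validation, LLT classification,
# goal attainment.

test_that("write_cohort / read_cohort round-trips are field-identical", {
  path <- withr::local_tempfile(fileext = ".csv")

  # empty cohort -> header-only file
  empty <- toy_cohort()[0, ]
  write_cohort(empty, path)
  expect_identical(length(readLines(path)), 1L)

  # one record -> two-line file
  write_cohort(toy_patient(), path)
  expect_identical(length(readLines(path)), 2L)

  # small hand-built cohort round-trips
  cohort <- toy_cohort(ldl = c(50.5, 60, 80.1))
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back, cohort, ignore_attr = TRUE)

  # synthetic cohort round-trips field-identically and byte-stably
  syn <- generate_cohort(default_cohort_spec(n = 100, seed = 42))
  write_cohort(syn, path)
  back <- read_cohort(path)
  expect_identical(nrow(back), 100L)
  expect_equal(back, syn, ignore_attr = TRUE)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("invalid rows are excluded with row-indexed reports", {
  cohort <- toy_cohort(ldl = c(50, -5, 80))
  path <- withr::local_tempfile(fileext = ".csv")
  # bypass write-side validation to craft a bad file
  out <- cohort
  for (col in c("diabetes", "hypertension", "chf", "af", "ckd_ge3",
                "event_within_1y", "ezetimibe", "pcsk9i", "other_llt"))
    out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  expect_warning(back <- read_cohort(path), "1 invalid row")
  expect_identical(nrow(back), 2L)
  errs <- attr(back, "row_errors")
  expect_identical(errs$row, 2L)
  expect_match(errs$problem, "ldl_c")
})

test_that("read_cohort fails fast on structural problems", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,ldl_c\nP1,90", path)
  expect_error(read_cohort(path), "missing required column")
  writeLines(character(0), path)
  expect_error(read_cohort(path))
  expect_error(read_cohort(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("validation enforces the record invariants", {
  expect_error(validate_cohort(toy_patient(age = 112)), "age")
  expect_error(validate_cohort(toy_patient(n_vascular_beds = 4)),
               "vascular_beds")
  expect_error(validate_cohort(toy_patient(ascvd_subtype = "XXX")),
               "ascvd_subtype")
  expect_error(
    validate_cohort(toy_patient(statin_intensity = "none")),
    "no lipid-lowering therapy")
})

test_that("classify_llt follows the combination-category footnotes", {
  # ezetimibe on top of moderate/high/unknown statin is an ezetimibe combo
  expect_identical(classify_llt("high", TRUE, FALSE, FALSE),
                   "ezetimibe_combo")
  expect_identical(classify_llt("unknown", TRUE, FALSE, FALSE),
                   "ezetimibe_combo")
  # PCSK9i with ezetimibe (no statin) is a PCSK9i combo
  expect_identical(classify_llt("none", TRUE, TRUE, FALSE), "pcsk9i_combo")
  # ezetimibe alone, or with a low-intensity statin, is other LLT
  expect_identical(classify_llt("none", TRUE, FALSE, FALSE), "other_llt")
  expect_identical(classify_llt("low", TRUE, FALSE, FALSE), "other_llt")
  # PCSK9i monotherapy is other LLT
  expect_identical(classify_llt("none", FALSE, TRUE, FALSE), "other_llt")
  # statin monotherapies
  expect_identical(classify_llt("moderate", FALSE, FALSE, FALSE),
                   "moderate_statin_mono")
  expect_error(classify_llt("none", FALSE, FALSE, FALSE),
               "no lipid-lowering therapy")
})

test_that("classify_llt is total and single-valued over all regimens", {
  grid <- expand.grid(statin = c("none", "low", "moderate", "high",
                                 "unknown"),
                      eze = c(FALSE, TRUE), pcsk9 = c(FALSE, TRUE),
                      other = c(FALSE, TRUE), stringsAsFactors = FALSE)
  has_llt <- grid$statin != "none" | grid$eze | grid$pcsk9 | grid$other
  grid <- grid[has_llt, ]
  expect_identical(nrow(grid), 39L)  # 2*5*2*2 minus the all-none case
  cats <- classify_llt(grid$statin, grid$eze, grid$pcsk9, grid$other)
  expect_true(all(cats %in% c("low_statin_mono", "moderate_statin_mono",
                              "high_statin_mono", "ezetimibe_combo",
                              "pcsk9i_combo", "other_llt")))
  expect_identical(length(cats), nrow(grid))
  # brute-force re-derivation of the precedence rules, case by case
  oracle <- apply(grid, 1, function(r) {
    statin <- r[["statin"]]
    eze <- as.logical(r[["eze"]]); p9 <- as.logical(r[["pcsk9"]])
    if (p9 && (statin != "none" || eze)) return("pcsk9i_combo")
    if (!p9 && eze && statin %in% c("moderate", "high", "unknown"))
      return("ezetimibe_combo")
    if (!p9 && !eze && statin %in% c("low", "moderate", "high"))
      return(paste0(statin, "_statin_mono"))
    "other_llt"
  })
  expect_identical(cats, unname(oracle))
})

test_that("goal attainment gives per-threshold proportions, monotone in t", {
  cohort <- toy_cohort(ldl = c(50, 60, 80))
  ga <- goal_attainment(cohort, thresholds = c(70, 55))
  ov <- ga[ga$group_type == "overall", ]
  expect_equal(ov$proportion[ov$threshold == 70], 2 / 3)
  expect_equal(ov$proportion[ov$threshold == 55], 1 / 3)
  expect_error(goal_attainment(cohort[0, ]), "empty")
  expect_error(goal_attainment(cohort, thresholds = -1), "positive")

  # monotonicity across nested thresholds on a synthetic cohort
  syn <- generate_cohort(default_cohort_spec(n = 500, seed = 7))
  ga <- goal_attainment(syn, thresholds = c(40, 55, 70, 100))
  ov <- ga[ga$group_type == "overall", ]
  expect_true(all(diff(ov$proportion[order(ov$threshold)]) >= 0))
})

test_that("calibrated synthetic cohort reproduces published attainment", {
  cohort <- generate_cohort(default_cohort_spec())
  ga <- goal_attainment(cohort, thresholds = c(70, 55))
  ov <- ga[ga$group_type == "overall", ]
  expect_lt(abs(ov$proportion[ov$threshold == 70] - 0.39), 0.03)
  expect_lt(abs(ov$proportion[ov$threshold == 55] - 0.19), 0.03)
})
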