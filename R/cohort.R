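# Cohort container, validation, CSV I/O, LLT classification and goal
# attainment.
#
# A cohort is a plain data.frame, one row per secondary-prevention ASCVD
# patient, holding the covariates the risk equation needs, the LDL-C level,
# and the lipid-lowering-therapy (LLT) regimen at the time the LDL-C was
# measured. Booleans are stored as logical in R and serialized as 0/1 in CSV
# so round-trips are deterministic.

ASCVD_SUBTYPES <- c("CAD", "CBD", "PAD")
SEX_LEVELS <- c("female", "male")
SMOKING_LEVELS <- c("non", "ex", "light", "moderate", "heavy")
STATIN_LEVELS <- c("none", "low", "moderate", "high", "unknown")
LLT_CATEGORIES <- c("low_statin_mono", "moderate_statin_mono",
                    "high_statin_mono", "ezetimibe_combo", "pcsk9i_combo",
                    "other_llt")

COHORT_COLUMNS <- c(
  "patient_id", "ascvd_subtype", "ldl_c", "age", "sex", "smoking",
  "diabetes", "hypertension", "chf", "af", "sbp", "dbp", "bmi", "ckd_ge3",
  "n_vascular_beds", "event_within_1y", "region",
  "statin_intensity", "ezetimibe", "pcsk9i", "other_llt")

COHORT_LOGICAL <- c("diabetes", "hypertension", "chf", "af", "ckd_ge3",
                    "event_within_1y", "ezetimibe", "pcsk9i", "other_llt")
COHORT_NUMERIC <- c("ldl_c", "age", "sbp", "dbp", "bmi", "n_vascular_beds")

# Per-row validation; returns a character vector of problems (empty if valid).
validate_patient_row <- function(row) {
  problems <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(!is.na(row$ldl_c) && row$ldl_c > 0, "ldl_c must be > 0")
  chk(!is.na(row$age) && row$age >= 18 && row$age <= 110,
      "age must be in [18, 110]")
  chk(row$ascvd_subtype %in% ASCVD_SUBTYPES,
      "ascvd_subtype must be one of CAD, CBD, PAD")
  chk(row$sex %in% SEX_LEVELS, "sex must be female or male")
  chk(row$smoking %in% SMOKING_LEVELS,
      "smoking must be one of non, ex, light, moderate, heavy")
  chk(row$statin_intensity %in% STATIN_LEVELS,
      "statin_intensity must be one of none, low, moderate, high, unknown")
  chk(!is.na(row$n_vascular_beds) && row$n_vascular_beds %in% 1:3,
      "n_vascular_beds must be 1, 2 or 3")
  chk(!is.na(row$sbp) && row$sbp > 0, "sbp must be > 0")
  chk(!is.na(row$dbp) && row$dbp > 0, "dbp must be > 0")
  chk(!is.na(row$bmi) && row$bmi > 0, "bmi must be > 0")
  for (col in COHORT_LOGICAL)
    chk(!is.na(row[[col]]), paste0(col, " must be 0/1"))
  # study inclusion: every patient is on some LLT
  if (row$statin_intensity %in% STATIN_LEVELS &&
      !anyNA(c(row$ezetimibe, row$pcsk9i, row$other_llt)))
    chk(row$statin_intensity != "none" || row$ezetimibe || row$pcsk9i ||
          row$other_llt,
        "regimen has no lipid-lowering therapy (study inclusion violated)")
  problems
}

#' Validate a cohort data.frame
#'
#' Checks column presence, types and per-row invariants (positive LDL-C,
#' age in 18-110, known factor levels, 1-3 vascular beds, at least one
#' lipid-lowering therapy per patient).
#'
#' @param cohort A data.frame with the columns listed in the package's
#'   column dictionary (see [read_cohort()]).
#' @param action `"error"` to stop on the first invalid row, `"report"` to
#'   drop invalid rows with a warning and attach the problems as the
#'   `"row_errors"` attribute.
#' @return The validated cohort (invisibly the same object for valid input).
#' @export
validate_cohort <- function(cohort, action = c("error", "report")) {
  action <- match.arg(action)
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(cohort) == 0) return(cohort[, COHORT_COLUMNS, drop = FALSE])
  bad <- list()
  for (i in seq_len(nrow(cohort))) {
    problems <- validate_patient_row(cohort[i, ])
    if (length(problems)) {
      msg <- paste0("row ", i, " (", cohort$patient_id[i], "): ",
                    paste(problems, collapse = "; "))
      if (action == "error") stop(msg)
      bad[[length(bad) + 1L]] <- data.frame(row = i, problem = msg,
                                            stringsAsFactors = FALSE)
    }
  }
  errs <- if (length(bad)) do.call(rbind, bad) else NULL
  if (!is.null(errs)) {
    warning(nrow(errs), " invalid row(s) excluded from cohort")
    cohort <- cohort[-errs$row, , drop = FALSE]
    rownames(cohort) <- NULL
  }
  out <- cohort[, c(COHORT_COLUMNS, setdiff(names(cohort), COHORT_COLUMNS)),
                drop = FALSE]
  attr(out, "row_errors") <- errs
  out
}

#' Read a patient cohort from CSV
#'
#' Reads a comma-separated, UTF-8, headered cohort file (one row per
#' patient; booleans coded 0/1) and validates every row. Invalid rows are
#' excluded with a per-row warning naming the row index; the remaining rows
#' keep their file order.
#'
#' @param path Path to a CSV file written by [write_cohort()] or following
#'   the same column dictionary: `patient_id`, `ascvd_subtype` (CAD/CBD/PAD),
#'   `ldl_c` (mg/dl), `age` (years), `sex`, `smoking`, `diabetes`,
#'   `hypertension`, `chf`, `af`, `sbp`, `dbp` (mmHg), `bmi` (kg/m^2),
#'   `ckd_ge3`, `n_vascular_beds` (1-3), `event_within_1y`, `region`,
#'   `statin_intensity`, `ezetimibe`, `pcsk9i`, `other_llt`.
#' @return A validated cohort data.frame. Excluded rows, if any, are
#'   reported in the `"row_errors"` attribute.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) == 0 && ncol(raw) == 0) stop("empty cohort file: ", path)
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  for (col in COHORT_NUMERIC) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    raw[[col]] <- v
  }
  for (col in COHORT_LOGICAL) {
    v <- rep(NA, nrow(raw))
    v[raw[[col]] %in% c("1", "TRUE", "true")] <- TRUE
    v[raw[[col]] %in% c("0", "FALSE", "false")] <- FALSE
    raw[[col]] <- v
  }
  validate_cohort(raw, action = "report")
}

#' Write a patient cohort to CSV
#'
#' Writes the cohort with a stable column order and booleans coded 0/1, so
#' that `read_cohort(write_cohort(x))` reproduces `x` field-by-field and
#' repeated writes of the same cohort are byte-identical.
#'
#' @param cohort A validated cohort data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  out <- cohort[, COHORT_COLUMNS, drop = FALSE]
  for (col in COHORT_LOGICAL) out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Classify a lipid-lowering-therapy regimen
#'
#' Maps each regimen (statin intensity, ezetimibe, PCSK9 inhibitor, other
#' agent) to exactly one of six mutually exclusive combination-therapy
#' categories, following the convention used in observational LLT tables:
#'
#' * any PCSK9i together with a statin and/or ezetimibe -> `pcsk9i_combo`;
#' * ezetimibe with a moderate-, high- or unknown-intensity statin ->
#'   `ezetimibe_combo`;
#' * statin monotherapy of low/moderate/high intensity -> the matching
#'   `*_statin_mono` category;
#' * everything else with at least one therapy (ezetimibe without statin,
#'   PCSK9i alone, ezetimibe with a low-intensity statin, unknown-intensity
#'   statin monotherapy, fibrates/fish oils alone) -> `other_llt`.
#'
#' @param statin_intensity Character vector with levels
#'   `none/low/moderate/high/unknown`.
#' @param ezetimibe,pcsk9i,other_llt Logical vectors.
#' @return Character vector of categories (see `LLT_CATEGORIES`).
#' @export
#' @examples
#' classify_llt("high", ezetimibe = TRUE, pcsk9i = FALSE, other_llt = FALSE)
classify_llt <- function(statin_intensity, ezetimibe, pcsk9i, other_llt) {
  n <- length(statin_intensity)
  stopifnot(length(ezetimibe) == n, length(pcsk9i) == n,
            length(other_llt) == n)
  if (!all(statin_intensity %in% STATIN_LEVELS))
    stop("unknown statin_intensity level")
  any_llt <- statin_intensity != "none" | ezetimibe | pcsk9i | other_llt
  if (any(!any_llt))
    stop("regimen with no lipid-lowering therapy at row(s) ",
         paste(which(!any_llt), collapse = ", "),
         " (study inclusion requires prescribed LLT)")
  out <- rep("other_llt", n)
  statin_any <- statin_intensity != "none"
  out[pcsk9i & (statin_any | ezetimibe)] <- "pcsk9i_combo"
  sel <- !pcsk9i & ezetimibe & statin_intensity %in%
    c("moderate", "high", "unknown")
  out[sel] <- "ezetimibe_combo"
  mono <- !pcsk9i & !ezetimibe
  out[mono & statin_intensity == "low"] <- "low_statin_mono"
  out[mono & statin_intensity == "moderate"] <- "moderate_statin_mono"
  out[mono & statin_intensity == "high"] <- "high_statin_mono"
  out
}

#' LDL-C goal attainment, overall and stratified
#'
#' For each threshold, the proportion of patients with LDL-C strictly below
#' it, computed for the whole cohort, within each ASCVD subtype, and within
#' each LLT combination category.
#'
#' @param cohort A validated cohort data.frame.
#' @param thresholds Strictly positive LDL-C thresholds in mg/dl
#'   (default `c(70, 55)`, the two guideline levels).
#' @return A data.frame with columns `group_type`
#'   (`overall`/`ascvd_subtype`/`llt_category`), `group`, `threshold`, `n`
#'   and `proportion`.
#' @export
goal_attainment <- function(cohort, thresholds = c(70, 55)) {
  if (nrow(cohort) == 0) stop("empty cohort")
  if (any(thresholds <= 0)) stop("thresholds must be strictly positive")
  cat_llt <- classify_llt(cohort$statin_intensity, cohort$ezetimibe,
                          cohort$pcsk9i, cohort$other_llt)
  groups <- rbind(
    data.frame(group_type = "overall", group = "overall",
               key = "overall", stringsAsFactors = FALSE),
    data.frame(group_type = "ascvd_subtype", group = ASCVD_SUBTYPES,
               key = ASCVD_SUBTYPES, stringsAsFactors = FALSE),
    data.frame(group_type = "llt_category", group = LLT_CATEGORIES,
               key = LLT_CATEGORIES, stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- switch(groups$group_type[i],
                  overall = rep(TRUE, nrow(cohort)),
                  ascvd_subtype = cohort$ascvd_subtype == groups$group[i],
                  llt_category = cat_llt == groups$group[i])
    data.frame(group_type = groups$group_type[i], group = groups$group[i],
               threshold = thresholds, n = sum(sel),
               proportion = if (sum(sel) == 0) NA_real_ else
                 vapply(thresholds,
                        function(t) mean(cohort$ldl_c[sel] < t), 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
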