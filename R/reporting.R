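# Median/IQR summaries stratified by cohort, ASCVD subtype and scenario.

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics (quantile
#' position `1 + (n - 1) * p`, [stats::quantile()] type 7), the common
#' default in scientific software; the convention is fixed so that golden
#' outputs are stable.
#'
#' @param values Nonempty numeric vector.
#' @return A `"summary_stat"` list: `median`, `q1`, `q3`, `n`.
#' @export
#' @examples
#' median_iqr(1:4)  # median 2.5, IQR (1.75, 3.25)
median_iqr <- function(values) {
  if (length(values) == 0) stop("cannot summarize an empty vector")
  if (anyNA(values)) stop("values contain NA")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 n = length(values)),
            class = "summary_stat")
}

#' @export
format.summary_stat <- function(x, digits = 3, ...) {
  sprintf("%s (%s-%s), n=%d",
          format(x$median, digits = digits),
          format(x$q1, digits = digits),
          format(x$q3, digits = digits), x$n)
}

#' @export
print.summary_stat <- function(x, ...) {
  cat("median (IQR):", format(x), "\n")
  invisible(x)
}

REPORT_QUANTITIES <- c("delta_ldl", "rel_reduction", "rrr", "arr",
                       "residual_p120", "baseline_p120")
PERCENT_QUANTITIES <- c("rel_reduction", "rrr", "arr", "residual_p120",
                        "baseline_p120")

#' Build a stratified simulation report
#'
#' Summarizes every simulated quantity (LDL-C gap, relative reduction, RRR,
#' ARR, residual and baseline 10-year risk) as median/IQR per stratum
#' (overall plus each ASCVD subtype) and scenario. Fractions additionally
#' carry integer-percent renderings (half-away-from-zero), matching the
#' presentation convention of published tables; raw fractions are retained.
#'
#' @param results Output of [simulate_scenario()] / [simulate_goals()].
#' @param cohort The cohort the results were simulated from (supplies the
#'   subtype of each patient).
#' @return A data.frame with columns `stratum`, `scenario`, `quantity`,
#'   `n`, `median`, `q1`, `q3`, `median_pct`, `q1_pct`, `q3_pct` (percent
#'   columns NA for mg/dl quantities). Strata with no results keep their
#'   rows with `n = 0` and NA statistics.
#' @export
build_report <- function(results, cohort) {
  unknown <- setdiff(unique(results$patient_id), cohort$patient_id)
  if (length(unknown))
    stop("results reference unknown patient_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  subtype <- cohort$ascvd_subtype[match(results$patient_id,
                                        cohort$patient_id)]
  strata <- c("overall", ASCVD_SUBTYPES)
  scenarios <- unique(results$scenario)
  rows <- list()
  for (st in strata) {
    sel <- if (st == "overall") rep(TRUE, nrow(results)) else subtype == st
    for (sc in scenarios) {
      sel2 <- sel & results$scenario == sc
      for (qn in REPORT_QUANTITIES) {
        v <- results[[qn]][sel2]
        if (length(v)) {
          s <- median_iqr(v)
          row <- data.frame(stratum = st, scenario = sc, quantity = qn,
                            n = s$n, median = s$median, q1 = s$q1,
                            q3 = s$q3, stringsAsFactors = FALSE)
        } else {
          row <- data.frame(stratum = st, scenario = sc, quantity = qn,
                            n = 0L, median = NA_real_, q1 = NA_real_,
                            q3 = NA_real_, stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  report <- do.call(rbind, rows)
  is_pct <- report$quantity %in% PERCENT_QUANTITIES
  pct <- function(col) ifelse(is_pct, round_half_up(report[[col]] * 100),
                              NA_real_)
  report$median_pct <- pct("median")
  report$q1_pct <- pct("q1")
  report$q3_pct <- pct("q3")
  report
}

#' Write report tables
#'
#' Writes the tidy report as `summary.csv` plus one human-readable
#' markdown table per stratum (`report_<stratum>.md`). Output is
#' byte-stable for identical inputs.
#'
#' @param report Output of [build_report()].
#' @param path Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
render_tables <- function(report, path) {
  if (nrow(report) == 0) stop("empty report")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(path, "summary.csv")
  out <- report
  for (col in c("median", "q1", "q3"))
    out[[col]] <- formatC(out[[col]], digits = 10, format = "g")
  utils::write.csv(out, files, row.names = FALSE, quote = FALSE)
  fmt_cell <- function(r) {
    if (r$n == 0) return("-")
    if (r$quantity %in% PERCENT_QUANTITIES)
      sprintf("%d%% (%d-%d%%)", r$median_pct, r$q1_pct, r$q3_pct)
    else
      sprintf("%.0f (%.0f-%.0f) mg/dl",
              round_half_up(r$median), round_half_up(r$q1),
              round_half_up(r$q3))
  }
  for (st in unique(report$stratum)) {
    sub <- report[report$stratum == st, , drop = FALSE]
    lines <- c(paste0("# Stratum: ", st), "",
               "| scenario | quantity | median (IQR) | n |",
               "|---|---|---|---|")
    for (i in seq_len(nrow(sub)))
      lines <- c(lines, sprintf("| %s | %s | %s | %d |",
                                sub$scenario[i], sub$quantity[i],
                                fmt_cell(sub[i, ]), sub$n[i]))
    f <- file.path(path, paste0("report_", st, ".md"))
    writeLines(lines, f)
    files <- c(files, f)
  }
  invisible(files)
}
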