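#' Read and validate a clinical table
#'
#' Clinical records carry the outcome data used downstream: preoperative
#' CA125 (U/mL), FIGO stage, histology, disease-free survival (DFS: time from
#' treatment to relapse/progression) and overall survival (OS: time to death),
#' and germline BRCA1/2 status. Unknown values are permitted as `NA` (or the
#' literal string `unknown` for `brca_status`) and are dropped from the
#' relevant summary denominators.
#'
#' @param path CSV with header columns `patient_id`, `ca125`, `figo_stage`,
#'   `histology`, `dfs_months`, `dfs_event`, `os_months`, `os_event`,
#'   `brca_status`.
#' @return a `clinical_table` data frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_giscan("clinical file not found: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_clinical(tab)
}

validate_clinical <- function(tab) {
  required <- c("patient_id", "ca125", "figo_stage", "histology",
                "dfs_months", "dfs_event", "os_months", "os_event",
                "brca_status")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop_giscan("clinical table is missing columns: %s",
                paste(missing, collapse = ", "))
  if (anyDuplicated(tab$patient_id))
    stop_giscan("duplicate patient_id in clinical table")
  num <- function(x) suppressWarnings(as.numeric(x))
  tab$ca125 <- num(tab$ca125)
  tab$dfs_months <- num(tab$dfs_months)
  tab$os_months <- num(tab$os_months)
  tab$dfs_event <- as.integer(tab$dfs_event)
  tab$os_event <- as.integer(tab$os_event)
  ok_stage <- is.na(tab$figo_stage) | tab$figo_stage %in% c("I", "II", "III", "IV")
  if (!all(ok_stage)) stop_giscan("figo_stage must be I/II/III/IV or NA")
  ok_hist <- is.na(tab$histology) |
    tab$histology %in% c("HGSC", "LGSC", "mucinous", "endometrioid", "clear_cell")
  if (!all(ok_hist)) stop_giscan("unrecognised histology value")
  for (ev in c("dfs_event", "os_event")) {
    if (any(!is.na(tab[[ev]]) & !tab[[ev]] %in% c(0L, 1L)))
      stop_giscan("%s must be 0/1", ev)
  }
  if (any(!is.na(tab$ca125) & tab$ca125 <= 0))
    stop_giscan("ca125 must be positive")
  both <- !is.na(tab$dfs_months) & !is.na(tab$os_months)
  if (any(tab$dfs_months[both] > tab$os_months[both] + 1e-9))
    stop_giscan("dfs_months exceeds os_months for: %s",
                paste(tab$patient_id[both & tab$dfs_months > tab$os_months],
                      collapse = ", "))
  tab$brca_status[is.na(tab$brca_status)] <- "unknown"
  if (!all(tab$brca_status %in% c("pathogenic", "wild_type", "unknown")))
    stop_giscan("brca_status must be pathogenic/wild_type/unknown")
  class(tab) <- c("clinical_table", "data.frame")
  tab
}

#' Summarise a clinical cohort
#'
#' Computes the cohort-composition arithmetic reported alongside such studies:
#' median CA125 over observed values, stage and histology counts, recurrence
#' (DFS events) and pathogenic-BRCA counts. Percentages derived from these
#' counts (see [cohort_percent()]) round half-up, so 29/40 prints as 73.
#' Unknown values are excluded from the affected category but the patient
#' still counts toward `n`.
#'
#' @param records a `clinical_table` (or plain data frame with its columns).
#' @return a `cohort_summary` list: `n`, `median_ca125`, `stage_counts`,
#'   `histology_counts`, `recurrence_count`, `brca_count`.
#' @export
summarize_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop_giscan("summarize_cohort requires at least one record")
  stages <- c("I", "II", "III", "IV")
  hists <- c("HGSC", "LGSC", "mucinous", "endometrioid", "clear_cell")
  stage_counts <- vapply(stages, function(s)
    sum(records$figo_stage == s, na.rm = TRUE), integer(1))
  hist_counts <- vapply(hists, function(h)
    sum(records$histology == h, na.rm = TRUE), integer(1))
  out <- list(
    n = nrow(records),
    median_ca125 = median(records$ca125, na.rm = TRUE),
    stage_counts = stage_counts,
    histology_counts = hist_counts,
    recurrence_count = sum(records$dfs_event == 1L, na.rm = TRUE),
    brca_count = sum(records$brca_status == "pathogenic", na.rm = TRUE)
  )
  class(out) <- "cohort_summary"
  out
}

#' Printed percentage for a cohort count
#'
#' @param count numerator.
#' @param n denominator.
#' @param digits decimal places (default 1, then trailing zeros trimmed by
#'   the caller; integer percentages use `digits = 0`).
#' @return half-up-rounded percentage on the 0-100 scale.
#' @export
cohort_percent <- function(count, n, digits = 0) {
  round_half_up(100 * count / n, digits)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$n))
  cat(sprintf("  median CA125: %.1f U/mL\n", x$median_ca125))
  cat("  FIGO stage:  ",
      paste(sprintf("%s=%d", names(x$stage_counts), x$stage_counts),
            collapse = "  "), "\n")
  cat("  histology:   ",
      paste(sprintf("%s=%d", names(x$histology_counts), x$histology_counts),
            collapse = "  "), "\n")
  adv <- sum(x$stage_counts[c("III", "IV")])
  cat(sprintf("  stage III/IV: %d (%d%%)\n", adv, cohort_percent(adv, x$n)))
  cat(sprintf("  recurrence/progression: %d (%d%%)\n", x$recurrence_count,
              cohort_percent(x$recurrence_count, x$n)))
  cat(sprintf("  BRCA1/2 pathogenic: %d (%d%%)\n", x$brca_count,
              cohort_percent(x$brca_count, x$n)))
  invisible(x)
}

#' Write a clinical table to CSV
#'
#' @param records a `clinical_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
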