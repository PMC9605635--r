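#' Read and validate a patient cohort table
#'
#' Reads a cohort CSV with one row per patient carrying clinical covariates
#' and overall/progression-free survival outcomes. Rows violating the record
#' invariants (negative survival times, progression after death when both
#' events are observed) are rejected with row-level diagnostics rather than
#' failing the whole load. When a raw `ki67_pct` column is supplied, the
#' dichotomous `ki67_high` marker is derived at the 20% positively stained
#' cells cutoff used to separate low from high proliferation.
#'
#' Expected columns:
#' `patient_id, age, ecog, resection, stupp_complete, ki67_pct, who_grade,
#' os_months, os_event, pfs_months, pfs_event`. Mandatory:
#' `patient_id, age, os_months, os_event, pfs_months, pfs_event`.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated records, one row per retained patient, with
#'   attribute `"rejected"` holding a tibble of dropped rows and the reason.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(raw)
}

#' Validate an in-memory cohort table
#'
#' Same checks as [read_cohort()] applied to a data frame already in memory;
#' the first argument is the data so the function pipes.
#'
#' @param data A data frame of cohort records.
#' @return A validated tibble; rejected rows in attribute `"rejected"`.
#' @export
validate_cohort <- function(data) {
  data <- tibble::as_tibble(data)
  mandatory <- c("patient_id", "age", "os_months", "os_event",
                 "pfs_months", "pfs_event")
  missing_cols <- setdiff(mandatory, names(data))
  if (length(missing_cols)) {
    stop("cohort table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data$os_event <- as.logical(data$os_event)
  data$pfs_event <- as.logical(data$pfs_event)
  if ("stupp_complete" %in% names(data)) {
    data$stupp_complete <- as.logical(data$stupp_complete)
  }
  if ("ki67_pct" %in% names(data) && !"ki67_high" %in% names(data)) {
    data$ki67_high <- data$ki67_pct >= 20
  }

  reason <- rep(NA_character_, nrow(data))
  bad_os <- !is.finite(data$os_months) | data$os_months < 0
  bad_pfs <- !is.finite(data$pfs_months) | data$pfs_months < 0
  reason[bad_os] <- "negative or non-finite os_months"
  reason[bad_pfs & is.na(reason)] <- "negative or non-finite pfs_months"
  ordered_bad <- !is.na(reason) |
    (data$os_event & data$pfs_event &
       data$pfs_months > data$os_months + 1e-9)
  reason[is.na(reason) & ordered_bad] <- "pfs_months exceeds os_months with both events observed"

  rejected <- data[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  kept <- data[is.na(reason), , drop = FALSE]
  if (nrow(rejected)) {
    message(nrow(rejected), " cohort row(s) rejected; see attr(x, 'rejected')")
  }
  attr(kept, "rejected") <- rejected
  kept
}
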