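RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD")

#' Normalize a treatment-response string to CR/PR/SD/PD
#'
#' Maps the verbatim tumor-board categories ("complete response",
#' "partial response", "stable disease", "progress"/"progressive disease")
#' onto the four RECIST-style codes. A string starting with "progress" is
#' progressive disease even when it carries a parenthetical iRECIST
#' annotation, mirroring the clinical-decision rule used for the cohort.
#'
#' @param x Character vector of response strings.
#' @return Character vector with values in `c("CR","PR","SD","PD")`.
#' @export
normalize_response <- function(x) {
  y <- tolower(trimws(as.character(x)))
  out <- ifelse(y %in% tolower(RESPONSE_LEVELS), toupper(y), NA_character_)
  out[y == "complete response"] <- "CR"
  out[y == "partial response"] <- "PR"
  out[y == "stable disease"] <- "SD"
  out[startsWith(y, "progress")] <- "PD"
  if (any(is.na(out)))
    stop("unrecognized response value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

required_cohort_columns <- c("patient_id", "sex", "age", "height", "weight",
                             "dose_mbq", "response", "os_days", "died")

validate_cohort <- function(df) {
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id values in cohort table")
  if (any(!df$sex %in% c("m", "f"))) stop("sex must be 'm' or 'f'")
  if (any(!is.finite(df$os_days)) || any(df$os_days <= 0))
    stop("os_days must be positive")
  if (any(!df$response %in% RESPONSE_LEVELS))
    stop("response must be one of ", paste(RESPONSE_LEVELS, collapse = "/"))
  ok <- is.na(df$height) | df$height > 0
  ok2 <- is.na(df$weight) | df$weight > 0
  if (!all(ok) || !all(ok2)) stop("height and weight must be positive")
  invisible(df)
}

#' Load a cohort table from CSV
#'
#' The CSV must carry a header naming at least
#' `patient_id,sex,age,height,weight,dose_mbq,response,os_days,died`;
#' `risk` and `agent` columns are kept when present. Response strings are
#' normalized to CR/PR/SD/PD via [normalize_response()].
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of class `mel_cohort`, one row per patient.
#' @export
load_cohort_table <- function(path) {
  if (!file.exists(path)) stop("cannot read cohort table: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cohort table is not parseable CSV: ",
                             conditionMessage(e))
  )
  missing_cols <- setdiff(required_cohort_columns, names(df))
  if (length(missing_cols) > 0)
    stop("cohort table misses required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("cohort table has no rows")
  df$patient_id <- as.character(df$patient_id)
  df$response <- normalize_response(df$response)
  df$died <- as.logical(df$died)
  for (col in c("age", "height", "weight", "dose_mbq", "os_days"))
    df[[col]] <- as.numeric(df[[col]])
  df$os_days <- as.integer(df$os_days)
  if ("risk" %in% names(df)) df$risk <- tolower(as.character(df$risk))
  validate_cohort(df)
  class(df) <- c("mel_cohort", "data.frame")
  df
}

#' Write a cohort table to CSV
#'
#' @param cohort A cohort `data.frame`.
#' @param path Output path.
#' @export
save_cohort_table <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' The embedded 37-patient study cohort
#'
#' Returns the published baseline table of the 37 metastasized-melanoma
#' patients (sex, age, therapeutic agent, treatment response, overall
#' survival in days, death marker and printed risk group). Heights,
#' weights and injected doses were not published per patient and are left
#' `NA`; the synthetic-cohort generator fills them for simulated patients.
#'
#' @return A `mel_cohort` data.frame with 37 rows.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_cohort.csv", package = "melrisk",
                      mustWork = TRUE)
  load_cohort_table(path)
}
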