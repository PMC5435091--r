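# Patient-chart data model and JSON Lines interchange.

SEX_LEVELS <- c("female", "male", "unknown")
REFERENCE_LABELS <- c("definite_copd", "possible_copd", "copd_ruled_out", "no_mention")
CPP_SECTIONS <- c("problem_list", "past_medical_history")
RX_STATUS <- c("active", "inactive", "unknown")
SMOKING_STATUS <- c("current", "ex", "non", "unspecified")

copd_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "copd_error")))
}

as_chart_date <- function(x, field, allow_na = FALSE) {
  if (length(x) == 0 || (length(x) == 1 && (is.null(x) || is.na(x)))) {
    if (allow_na) return(as.Date(NA))
    copd_error(sprintf("field '%s' must be a date", field), "copd_validation_error")
  }
  d <- tryCatch(as.Date(x, format = "%Y-%m-%d"), error = function(e) as.Date(NA))
  if (anyNA(d) && !allow_na) {
    copd_error(sprintf("field '%s' has invalid date '%s'", field, paste(x, collapse = ",")),
               "copd_validation_error")
  }
  d
}

empty_df <- function(cols) {
  out <- lapply(cols, function(cl) if (cl == "Date") as.Date(character()) else character())
  structure(as.data.frame(out, stringsAsFactors = FALSE), names = names(cols))
}

cpp_entry_cols <- c(section = "character", text = "character", date = "Date")
billing_cols <- c(code = "character", date = "Date")
rx_cols <- c(raw_text = "character", date = "Date", status = "character")
smoking_cols <- c(status = "character", date = "Date")

coerce_records <- function(x, cols, field, enum_checks = list()) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0) {
    return(empty_df(cols))
  }
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  for (nm in names(cols)) {
    if (!nm %in% names(df)) {
      if (nm == "date" && field == "cpp_entries") df[[nm]] <- NA_character_
      else copd_error(sprintf("field '%s' records lack column '%s'", field, nm),
                      "copd_parse_error")
    }
    if (cols[[nm]] == "Date") {
      df[[nm]] <- as_chart_date(as.character(df[[nm]]), paste0(field, ".date"),
                                allow_na = (field == "cpp_entries"))
    } else {
      df[[nm]] <- as.character(df[[nm]])
    }
  }
  for (nm in names(enum_checks)) {
    bad <- !df[[nm]] %in% enum_checks[[nm]]
    if (any(bad)) {
      copd_error(sprintf("field '%s.%s' has invalid value '%s'", field, nm, df[[nm]][bad][1]),
                 "copd_validation_error")
    }
  }
  df[names(cols)]
}

#' Construct a patient chart
#'
#' A `patient_chart` holds one patient's EMR content: free-text entries from
#' the cumulative patient profile (CPP: problem list and past medical
#' history), dated diagnostic billing events, dated prescription texts,
#' structured smoking-history records, demographics, a flag for the presence
#' of a pulmonary function test, and an optional chart-abstraction reference
#' label.
#'
#' @param patient_id Non-empty identifier string, unique within a cohort.
#' @param birth_date Birth date (`Date` or "YYYY-MM-DD"); mandatory.
#' @param sex One of `"female"`, `"male"`, `"unknown"`.
#' @param cpp_entries Data frame with columns `section` (`"problem_list"` or
#'   `"past_medical_history"`), `text`, and optional `date`.
#' @param billing_events Data frame with columns `code` (diagnostic code as
#'   entered; compared on its normalized 3-character stem) and `date`.
#' @param prescriptions Data frame with columns `raw_text`, `date`, `status`
#'   (`"active"`, `"inactive"`, `"unknown"`).
#' @param smoking_records Data frame with columns `status` (`"current"`,
#'   `"ex"`, `"non"`, `"unspecified"`) and `date`.
#' @param pft_on_chart Logical: is a pulmonary function test result on the
#'   chart (presence only; reports are not parsed).
#' @param reference_label Optional abstraction label: `"definite_copd"`,
#'   `"possible_copd"`, `"copd_ruled_out"` or `"no_mention"`; `NA` for
#'   unlabeled charts (classification only, no evaluation).
#' @return An object of class `patient_chart`.
#' @examples
#' ch <- patient_chart("P1", "1950-06-01", "female",
#'   cpp_entries = data.frame(section = "problem_list", text = "COPD"))
#' @export
patient_chart <- function(patient_id, birth_date, sex = "unknown",
                          cpp_entries = NULL, billing_events = NULL,
                          prescriptions = NULL, smoking_records = NULL,
                          pft_on_chart = FALSE, reference_label = NA_character_) {
  if (!is.character(patient_id) || length(patient_id) != 1 ||
      is.na(patient_id) || !nzchar(trimws(patient_id))) {
    copd_error("field 'patient_id' must be a non-empty string", "copd_parse_error")
  }
  birth_date <- as_chart_date(birth_date, "birth_date")
  if (!sex %in% SEX_LEVELS) {
    copd_error(sprintf("field 'sex' must be one of %s", paste(SEX_LEVELS, collapse = "/")),
               "copd_validation_error")
  }
  if (!is.na(reference_label) && !reference_label %in% REFERENCE_LABELS) {
    copd_error("field 'reference_label' has an invalid value", "copd_validation_error")
  }
  chart <- structure(list(
    patient_id = patient_id,
    birth_date = birth_date,
    sex = sex,
    cpp_entries = coerce_records(cpp_entries, cpp_entry_cols, "cpp_entries",
                                 list(section = CPP_SECTIONS)),
    billing_events = coerce_records(billing_events, billing_cols, "billing_events"),
    prescriptions = coerce_records(prescriptions, rx_cols, "prescriptions",
                                   list(status = RX_STATUS)),
    smoking_records = coerce_records(smoking_records, smoking_cols, "smoking_records",
                                     list(status = SMOKING_STATUS)),
    pft_on_chart = isTRUE(pft_on_chart),
    reference_label = reference_label
  ), class = "patient_chart")
  validate_chart(chart)
}

#' @export
print.patient_chart <- function(x, ...) {
  cat(sprintf("<patient_chart %s> born %s, sex %s; %d CPP, %d billing, %d rx, %d smoking; label: %s\n",
              x$patient_id, format(x$birth_date), x$sex, nrow(x$cpp_entries),
              nrow(x$billing_events), nrow(x$prescriptions), nrow(x$smoking_records),
              ifelse(is.na(x$reference_label), "<none>", x$reference_label)))
  invisible(x)
}

validate_chart <- function(chart) {
  for (fld in c("cpp_entries", "billing_events", "prescriptions", "smoking_records")) {
    d <- chart[[fld]]$date
    d <- d[!is.na(d)]
    if (length(d) && any(d < chart$birth_date)) {
      copd_error(sprintf("patient '%s': %s date precedes birth_date", chart$patient_id, fld),
                 "copd_validation_error")
    }
  }
  if (any(!nzchar(normalize_billing_code(chart$billing_events$code)))) {
    copd_error(sprintf("patient '%s': empty billing code after normalization", chart$patient_id),
               "copd_validation_error")
  }
  chart
}

#' Normalize a diagnostic billing code
#'
#' Trims whitespace, uppercases, and strips any decimal subcode down to the
#' 3-character stem, so that subcoded claims such as `"491.2"` compare equal
#' to the 3-digit target `"491"`. Idempotent; the original string is retained
#' on the chart for audit.
#'
#' @param code Character vector of raw billing codes.
#' @return Character vector of normalized stems.
#' @examples
#' normalize_billing_code(c("491.2", " 496 ", "v72"))
#' @export
normalize_billing_code <- function(code) {
  x <- toupper(trimws(as.character(code)))
  x <- sub("\\..*$", "", x)
  substr(x, 1L, 3L)
}

#' Patient age in completed years at a date
#'
#' @param chart A `patient_chart`.
#' @param index_date Reference date.
#' @return Age in completed years.
#' @export
chart_age <- function(chart, index_date) {
  index_date <- as_chart_date(index_date, "index_date")
  b <- as.POSIXlt(chart$birth_date); i <- as.POSIXlt(index_date)
  age <- i$year - b$year
  before <- (i$mon < b$mon) | (i$mon == b$mon & i$mday < b$mday)
  age - as.integer(before)
}

#' Default cohort index date
#'
#' The latest event date appearing anywhere in the cohort (billing,
#' prescription, smoking or dated CPP entries); used as the default reference
#' date for the age >= 35 eligibility rule.
#'
#' @param cohort A list of `patient_chart` objects.
#' @return A `Date`.
#' @export
cohort_index_date <- function(cohort) {
  dates <- unlist(lapply(cohort, function(ch) {
    as.numeric(c(ch$billing_events$date, ch$prescriptions$date,
                 ch$smoking_records$date, ch$cpp_entries$date))
  }))
  dates <- dates[!is.na(dates)]
  if (!length(dates)) copd_error("cohort has no dated events to anchor an index date",
                                 "copd_validation_error")
  as.Date(max(dates), origin = "1970-01-01")
}

check_cohort_ids <- function(cohort) {
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    copd_error(sprintf("duplicate patient_id '%s' in cohort", dup[1]),
               "copd_cohort_error")
  }
  invisible(ids)
}

chart_to_json <- function(chart) {
  obj <- list(
    patient_id = chart$patient_id,
    birth_date = format(chart$birth_date, "%Y-%m-%d"),
    sex = chart$sex,
    cpp_entries = df_dates_to_char(chart$cpp_entries),
    billing_events = df_dates_to_char(chart$billing_events),
    prescriptions = df_dates_to_char(chart$prescriptions),
    smoking_records = df_dates_to_char(chart$smoking_records),
    pft_on_chart = chart$pft_on_chart,
    reference_label = chart$reference_label
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null", dataframe = "rows")
}

df_dates_to_char <- function(df) {
  if ("date" %in% names(df)) df$date <- format(df$date, "%Y-%m-%d")
  df
}

#' Write a cohort to the JSON Lines chart interchange format
#'
#' One patient per line; dates as "YYYY-MM-DD"; enums as lowercase strings.
#'
#' @param cohort List of `patient_chart` objects.
#' @param path Output file path or connection.
#' @return `path`, invisibly.
#' @export
write_charts <- function(cohort, path) {
  check_cohort_ids(cohort)
  lines <- vapply(cohort, function(ch) as.character(chart_to_json(ch)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort from the JSON Lines chart interchange format
#'
#' Every well-formed record yields one `patient_chart`; input order is
#' preserved. Malformed records raise a parse error naming the line; a
#' duplicated `patient_id` raises a cohort integrity error; event dates
#' before the birth date raise a validation error.
#'
#' @param path Input file path or connection.
#' @return List of `patient_chart` objects.
#' @export
read_charts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  cohort <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyDataFrame = TRUE),
      error = function(e) copd_error(sprintf("line %d: invalid JSON record (%s)",
                                             i, conditionMessage(e)), "copd_parse_error"))
    cohort[[i]] <- withCallingHandlers(
      record_to_chart(rec),
      copd_error = function(e) {
        copd_error(sprintf("line %d: %s", i, conditionMessage(e)), class(e)[1])
      })
  }
  check_cohort_ids(cohort)
  cohort
}

record_to_chart <- function(rec) {
  if (is.null(rec$patient_id)) {
    copd_error("field 'patient_id' is missing", "copd_parse_error")
  }
  if (is.null(rec$birth_date)) {
    copd_error("field 'birth_date' is missing", "copd_parse_error")
  }
  patient_chart(
    patient_id = as.character(rec$patient_id),
    birth_date = rec$birth_date,
    sex = if (is.null(rec$sex)) "unknown" else rec$sex,
    cpp_entries = rec$cpp_entries,
    billing_events = rec$billing_events,
    prescriptions = rec$prescriptions,
    smoking_records = rec$smoking_records,
    pft_on_chart = isTRUE(rec$pft_on_chart),
    reference_label = if (is.null(rec$reference_label) || is.na(rec$reference_label))
      NA_character_ else as.character(rec$reference_label)
  )
}
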