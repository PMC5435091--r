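# Chart-level atomic criteria: CPP documentation, billing-count windows,
# prescription classes, smoking status.

COPD_BILLING_CODES <- c("491", "492", "496")

#' Does the CPP document a COPD diagnosis?
#'
#' TRUE iff some CPP entry (problem list or past medical history) yields a
#' term match that is not excluded by uncertainty phrasing.
#'
#' @param chart A `patient_chart`.
#' @param lexicon A `copd_lexicon`.
#' @param lookback Passed to [match_copd_term()].
#' @return Logical.
#' @export
cpp_indicates_copd <- function(chart, lexicon, lookback = Inf) {
  txts <- chart$cpp_entries$text
  for (tx in txts) {
    m <- match_copd_term(tx, lexicon, lookback = lookback)
    if (m$matched && !m$excluded) return(TRUE)
  }
  FALSE
}

#' Billing-count criterion over the whole chart or a rolling window
#'
#' With `window_days = "ever"`, TRUE iff at least `min_count` billing events
#' carry a normalized code in `codes` anywhere on the chart. With a finite
#' window, TRUE iff some span of `window_days` consecutive days (both
#' endpoints inclusive) contains at least `min_count` qualifying events;
#' windows are anchored at each qualifying event date, which suffices
#' because a maximal window can always be slid left onto its earliest event.
#' `calendar_year = TRUE` switches "within 1 year" to calendar-year grouping
#' for sensitivity analysis.
#'
#' @param chart A `patient_chart`.
#' @param codes Non-empty character vector of target codes (normalized stems).
#' @param min_count Minimum qualifying events, >= 1.
#' @param window_days Window length in days, or `"ever"`.
#' @param dedup_same_day Count several same-day claims as one.
#' @param calendar_year Group by calendar year instead of a rolling window.
#' @return Logical.
#' @examples
#' ch <- patient_chart("P1", "1950-01-01", billing_events = data.frame(
#'   code = c("496", "491"), date = c("2009-01-10", "2009-06-01")))
#' billing_criterion_met(ch, c("491", "492", "496"), 2, 365)
#' @export
billing_criterion_met <- function(chart, codes, min_count = 1L,
                                  window_days = "ever",
                                  dedup_same_day = FALSE,
                                  calendar_year = FALSE) {
  stopifnot(length(codes) >= 1, min_count >= 1)
  codes <- normalize_billing_code(codes)
  ev <- chart$billing_events
  dates <- ev$date[normalize_billing_code(ev$code) %in% codes]
  if (dedup_same_day) dates <- unique(dates)
  if (length(dates) < min_count) return(FALSE)
  if (identical(window_days, "ever")) return(TRUE)
  if (calendar_year) {
    return(max(table(format(dates, "%Y"))) >= min_count)
  }
  stopifnot(is.numeric(window_days), window_days > 0)
  d <- sort(as.numeric(dates))
  for (anchor in d) {
    if (sum(d >= anchor & d <= anchor + window_days - 1) >= min_count) return(TRUE)
  }
  FALSE
}

#' Prescription criterion by drug class
#'
#' TRUE iff some prescription on the chart classifies into one of `classes`,
#' under scope `"ever"` (prescribed at any point in time) or `"active"`
#' (currently active prescriptions only).
#'
#' @param chart A `patient_chart`.
#' @param classes Subset of `"tiotropium"`, `"ipratropium"`,
#'   `"ipratropium_salbutamol"`.
#' @param scope `"ever"` or `"active"`.
#' @param lexicon A `copd_lexicon`.
#' @return Logical.
#' @export
drug_criterion_met <- function(chart, classes, scope = c("ever", "active"),
                               lexicon) {
  scope <- match.arg(scope)
  stopifnot(all(classes %in% setdiff(DRUG_CLASSES, "other")))
  rx <- chart$prescriptions
  if (scope == "active") rx <- rx[rx$status == "active", , drop = FALSE]
  for (tx in rx$raw_text) {
    if (classify_drug(tx, lexicon) %in% classes) return(TRUE)
  }
  FALSE
}

#' Positive smoking history (current or ex-smoker)
#'
#' Governed by the most recent smoking record: TRUE iff the most-recent-dated
#' record has status `"current"` or `"ex"`. No records, or a most recent
#' record of `"non"`/`"unspecified"`, give FALSE. Date ties go to the record
#' appearing later in chart order.
#'
#' @param chart A `patient_chart`.
#' @return Logical.
#' @export
smoking_positive <- function(chart) {
  sm <- chart$smoking_records
  if (nrow(sm) == 0) return(FALSE)
  latest <- max(which(sm$date == max(sm$date)))
  sm$status[latest] %in% c("current", "ex")
}
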