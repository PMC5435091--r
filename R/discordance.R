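# Mechanism taxonomy for algorithm/reference discordance: why false
# negatives were missed and what drove false positives.

FN_CATEGORIES <- c("uncertainty_phrasing", "incomplete_cpp", "insufficient_billing", "other")
FP_CATEGORIES <- c("uncertainty_phrasing", "billing_only", "ambiguous_or_stale_cpp", "other")

#' Categorize one discordant chart
#'
#' For a false negative (reference definite COPD, algorithm negative), in
#' priority order: a COPD term present in the CPP but excluded by
#' uncertainty phrasing ("?"/"possible") gives `uncertainty_phrasing`; no
#' CPP COPD language at all gives `incomplete_cpp` (the chart's diagnosis
#' lives outside the profile); COPD billing present but below the
#' algorithm's threshold gives `insufficient_billing`; anything else
#' `other`. For a false positive: positive solely through billing leaves
#' with no CPP or prescription evidence gives `billing_only`; positive via a
#' CPP mention whose entry carries compound or hedged phrasing that the
#' strict exclusion rules do not catch (e.g. "Asthma/COPD", "r/o", "rule
#' out", "query") gives `ambiguous_or_stale_cpp`; anything else `other`.
#'
#' @param chart A labeled `patient_chart`.
#' @param result The `algorithm_result` for this chart (or one row of
#'   [classify_cohort()] output).
#' @param lexicon A `copd_lexicon`.
#' @return A `discordance_record`: list with `patient_id`, `error_type`,
#'   `category`, `evidence`.
#' @export
categorize_discordant <- function(chart, result, lexicon) {
  positive <- if (is.list(result) && !is.null(result$positive)) isTRUE(result$positive[1])
              else copd_error("result lacks 'positive'", "copd_validation_error")
  fired <- result$fired_criteria
  if (is.character(fired) && length(fired) == 1 && grepl(";", fired)) {
    fired <- strsplit(fired, ";", fixed = TRUE)[[1]]
  }
  ref_pos <- identical(chart$reference_label, "definite_copd")
  if (positive == ref_pos) {
    copd_error(sprintf("chart '%s' is concordant; nothing to categorize",
                       chart$patient_id), "copd_contract_error")
  }
  if (ref_pos) fn_category(chart, lexicon) else fp_category(chart, fired, lexicon)
}

new_discordance_record <- function(patient_id, error_type, category, evidence) {
  structure(list(patient_id = patient_id, error_type = error_type,
                 category = category, evidence = evidence),
            class = "discordance_record")
}

fn_category <- function(chart, lexicon) {
  matches <- lapply(chart$cpp_entries$text, match_copd_term, lexicon = lexicon)
  excluded <- vapply(matches, function(m) m$matched && m$excluded, logical(1))
  any_match <- vapply(matches, `[[`, logical(1), "matched")
  copd_billing <- sum(normalize_billing_code(chart$billing_events$code) %in%
                        COPD_BILLING_CODES)
  if (any(excluded)) {
    ev <- chart$cpp_entries$text[excluded]
    cat_ <- "uncertainty_phrasing"
  } else if (!any(any_match)) {
    if (copd_billing >= 1) {
      ev <- sprintf("%d COPD billing code(s) below algorithm threshold", copd_billing)
      cat_ <- "insufficient_billing"
    } else {
      ev <- "no COPD language in CPP; no qualifying billing"
      cat_ <- "incomplete_cpp"
    }
  } else if (copd_billing >= 1) {
    ev <- sprintf("%d COPD billing code(s) below algorithm threshold", copd_billing)
    cat_ <- "insufficient_billing"
  } else {
    ev <- "no mechanism identified"
    cat_ <- "other"
  }
  new_discordance_record(chart$patient_id, "false_negative", cat_, ev)
}

fp_category <- function(chart, fired, lexicon) {
  fired <- fired[nzchar(fired)]
  billing_fired <- grepl("^billing\\[", fired)
  non_billing <- fired[!billing_fired]
  if (length(fired) && all(billing_fired)) {
    return(new_discordance_record(chart$patient_id, "false_positive", "billing_only",
                                  fired))
  }
  if ("cpp_mention" %in% non_billing) {
    hedged <- character()
    ext <- setdiff(uncertainty_markers_extended(), lexicon$uncertainty_markers)
    for (tx in chart$cpp_entries$text) {
      m <- match_copd_term(tx, lexicon)
      if (!m$matched || m$excluded) next
      norm <- squish(tx)
      compound <- grepl(paste0("[a-z0-9]\\s*/\\s*", escape_regex(m$matched_term)), norm) ||
        grepl(paste0(escape_regex(m$matched_term), "\\s*/\\s*[a-z0-9]"), norm)
      hedged_marker <- any(vapply(ext, function(mk) {
        if (grepl("[a-z0-9]", mk)) find_bounded(norm, mk) > 0
        else grepl(mk, norm, fixed = TRUE)
      }, logical(1)))
      if (compound || hedged_marker) hedged <- c(hedged, tx)
    }
    if (length(hedged)) {
      return(new_discordance_record(chart$patient_id, "false_positive",
                                    "ambiguous_or_stale_cpp", hedged))
    }
  }
  new_discordance_record(chart$patient_id, "false_positive", "other",
                         if (length(fired)) fired else "no criteria fired")
}

#' Discordance records for a classified cohort
#'
#' Runs [categorize_discordant()] over every discordant chart.
#'
#' @param cohort Labeled list of `patient_chart` objects.
#' @param results [classify_cohort()] output for one algorithm.
#' @param lexicon A `copd_lexicon`.
#' @return Data frame: `patient_id`, `error_type`, `category`, `evidence`.
#' @export
discordance_records <- function(cohort, results, lexicon) {
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  pred <- results$positive[match(ids, results$patient_id)]
  fired <- results$fired_criteria[match(ids, results$patient_id)]
  ref <- vapply(cohort, `[[`, character(1), "reference_label") == "definite_copd"
  disc <- which(pred != ref)
  recs <- lapply(disc, function(i) {
    categorize_discordant(cohort[[i]],
                          list(patient_id = ids[i], positive = pred[i],
                               fired_criteria = fired[i]),
                          lexicon)
  })
  data.frame(
    patient_id = vapply(recs, `[[`, character(1), "patient_id"),
    error_type = vapply(recs, `[[`, character(1), "error_type"),
    category = vapply(recs, `[[`, character(1), "category"),
    evidence = vapply(recs, function(r) paste(r$evidence, collapse = " | "),
                      character(1)),
    stringsAsFactors = FALSE)
}

#' Summarize discordance records
#'
#' Counts and percentages per (error type, category); percentages are of
#' each error type's total, to 1 decimal.
#'
#' @param records Data frame from [discordance_records()] (or a list of
#'   `discordance_record`s).
#' @return Data frame: `error_type`, `category`, `n`, `pct`.
#' @export
discordance_summary <- function(records) {
  if (inherits(records, "discordance_record")) records <- list(records)
  if (is.list(records) && !is.data.frame(records)) {
    records <- data.frame(
      error_type = vapply(records, `[[`, character(1), "error_type"),
      category = vapply(records, `[[`, character(1), "category"),
      stringsAsFactors = FALSE)
  }
  if (!nrow(records)) {
    return(data.frame(error_type = character(), category = character(),
                      n = integer(), pct = numeric(), stringsAsFactors = FALSE))
  }
  tab <- as.data.frame(table(error_type = records$error_type,
                             category = records$category),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  totals <- tapply(tab$Freq, tab$error_type, sum)
  out <- data.frame(error_type = tab$error_type, category = tab$category,
                    n = as.integer(tab$Freq),
                    pct = round_half_up(100 * tab$Freq / as.numeric(totals[tab$error_type]), 1),
                    stringsAsFactors = FALSE)
  out[order(out$error_type, -out$n), , drop = FALSE]
}
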