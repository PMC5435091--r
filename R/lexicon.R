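# COPD diagnosis-language and medication lexicons, term matching with
# uncertainty-phrasing exclusion, and drug classification.

DRUG_CLASSES <- c("tiotropium", "ipratropium", "ipratropium_salbutamol", "other")

#' Construct a lexicon
#'
#' @param diagnosis_terms Character vector of diagnosis terms (acronyms, full
#'   spellings, common misspellings). Stored lowercase.
#' @param uncertainty_markers Character vector of uncertainty markers (e.g.
#'   `"?"`, `"possible"`) whose occurrence before a matched term within the
#'   same entry excludes the match.
#' @param drugs Named character vector mapping drug-name variant (generic,
#'   trade name, misspelling) to a drug class: `"tiotropium"`,
#'   `"ipratropium"` or `"ipratropium_salbutamol"`.
#' @return An object of class `copd_lexicon`.
#' @seealso [default_lexicon()]
#' @export
copd_lexicon <- function(diagnosis_terms, uncertainty_markers, drugs) {
  diagnosis_terms <- tolower(trimws(diagnosis_terms))
  uncertainty_markers <- tolower(trimws(uncertainty_markers))
  if (any(!nzchar(diagnosis_terms)) || any(!nzchar(uncertainty_markers))) {
    copd_error("lexicon entries must be non-empty strings", "copd_validation_error")
  }
  drugs <- vapply(drugs, as.character, character(1))
  names(drugs) <- tolower(trimws(names(drugs)))
  if (any(!nzchar(names(drugs)))) {
    copd_error("drug variants must be non-empty strings", "copd_validation_error")
  }
  if (any(!drugs %in% setdiff(DRUG_CLASSES, "other"))) {
    copd_error("drug classes must be tiotropium/ipratropium/ipratropium_salbutamol",
               "copd_validation_error")
  }
  structure(list(diagnosis_terms = unique(diagnosis_terms),
                 uncertainty_markers = unique(uncertainty_markers),
                 drugs = drugs),
            class = "copd_lexicon")
}

#' Default COPD lexicon
#'
#' Diagnosis terms cover the acronym, full spellings, synonymous diagnoses
#' (emphysema, chronic bronchitis) and a shipped misspelling list; the drug
#' map covers the three COPD-specific anticholinergic bronchodilators
#' (tiotropium, ipratropium, combined ipratropium/salbutamol) under generic
#' and trade names. Short-acting beta-agonists such as salbutamol alone are
#' deliberately absent: they are not specific to COPD.
#'
#' Uncertainty markers default to `"?"` and `"possible"` — the phrasings the
#' exclusion rules are built around. `strict = TRUE` narrows the diagnosis
#' terms to COPD proper (dropping emphysema/chronic bronchitis free text and
#' misspellings), for sensitivity analyses of what counts as CPP
#' documentation.
#'
#' @param strict Logical; narrow to the strict term list.
#' @return A `copd_lexicon`.
#' @examples
#' lex <- default_lexicon()
#' match_copd_term("?COPD", lex)
#' @export
default_lexicon <- function(strict = FALSE) {
  terms <- c("copd", "c.o.p.d", "chronic obstructive pulmonary disease")
  if (!strict) {
    terms <- c(terms,
               "chronic obstructive lung disease",
               "chronic obstructive airways disease", "coad",
               "emphysema", "chronic bronchitis",
               # common misspellings seen in free-text problem lists
               "emphyzema", "emphasema", "empysema",
               "chronic bronchitus", "chronic obstructive pulmonary desease")
  }
  drugs <- c(
    "tiotropium" = "tiotropium",
    "tiotropium bromide" = "tiotropium",
    "tiotroprium" = "tiotropium",
    "spiriva" = "tiotropium",
    "spiriva handihaler" = "tiotropium",
    "spiriva respimat" = "tiotropium",
    "ipratropium" = "ipratropium",
    "ipratropium bromide" = "ipratropium",
    "ipratroprium" = "ipratropium",
    "ipatropium" = "ipratropium",
    "atrovent" = "ipratropium",
    "ipratropium/salbutamol" = "ipratropium_salbutamol",
    "ipratropium-salbutamol" = "ipratropium_salbutamol",
    "ipratropium and salbutamol" = "ipratropium_salbutamol",
    "ipratropium bromide/salbutamol" = "ipratropium_salbutamol",
    "salbutamol/ipratropium" = "ipratropium_salbutamol",
    "combivent" = "ipratropium_salbutamol",
    "combivent udv" = "ipratropium_salbutamol",
    "combivent respimat" = "ipratropium_salbutamol"
  )
  copd_lexicon(diagnosis_terms = terms,
               uncertainty_markers = c("?", "possible"),
               drugs = drugs)
}

#' Extended uncertainty markers
#'
#' Conservative extensions beyond the default `"?"`/`"possible"` pair, for
#' users who want a wider exclusion net: `"query"`, `"r/o"`, `"rule out"`.
#'
#' @return Character vector of markers.
#' @export
uncertainty_markers_extended <- function() c("?", "possible", "query", "r/o", "rule out")

#' Read a lexicon from a YAML or JSON configuration file
#'
#' The file holds lists `diagnosis_terms` and `uncertainty_markers` and a map
#' `drugs` from variant to class.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or `.json`).
#' @return A `copd_lexicon`.
#' @export
read_lexicon <- function(path) {
  cfg <- read_config(path)
  for (fld in c("diagnosis_terms", "uncertainty_markers", "drugs")) {
    if (is.null(cfg[[fld]])) {
      copd_error(sprintf("lexicon file lacks '%s'", fld), "copd_parse_error")
    }
  }
  copd_lexicon(unlist(cfg$diagnosis_terms), unlist(cfg$uncertainty_markers),
               unlist(cfg$drugs))
}

read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

squish <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", tolower(as.character(x))))
}

# boundary-aware first occurrence of a literal needle; returns start index or -1
find_bounded <- function(haystack, needle) {
  pat <- paste0("(?<![a-z0-9])", escape_regex(needle), "(?![a-z0-9])")
  m <- regexpr(pat, haystack, perl = TRUE)
  as.integer(m)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Match COPD diagnosis language in one free-text entry
#'
#' Boundary-aware, case-insensitive search of a single CPP entry for any
#' diagnosis term in the lexicon, with an uncertainty-phrasing exclusion
#' rule: the match is excluded when an uncertainty marker occurs in the same
#' entry *before* the term, within `lookback` tokens (default: the whole
#' entry). Qualifiers *after* the term — including slash-joined compounds
#' such as `"Asthma/COPD"` — never exclude; such entries still count as
#' positive documentation.
#'
#' @param text Free text (possibly empty).
#' @param lexicon A `copd_lexicon`.
#' @param lookback Maximum number of tokens between marker and term for the
#'   exclusion to act; `Inf` means anywhere earlier in the entry.
#' @return A `term_match`: list with `matched`, `excluded`, `matched_term`,
#'   `exclusion_trigger`.
#' @examples
#' lex <- default_lexicon()
#' match_copd_term("possible COPD", lex)
#' match_copd_term("Asthma/COPD", lex)
#' @export
match_copd_term <- function(text, lexicon, lookback = Inf) {
  stopifnot(inherits(lexicon, "copd_lexicon"))
  no_match <- structure(list(matched = FALSE, excluded = FALSE,
                             matched_term = NA_character_,
                             exclusion_trigger = NA_character_),
                        class = "term_match")
  if (length(text) != 1 || is.na(text)) return(no_match)
  norm <- squish(text)
  if (!nzchar(norm)) return(no_match)

  # earliest boundary-aware hit; ties broken toward the longest term
  terms <- lexicon$diagnosis_terms[order(-nchar(lexicon$diagnosis_terms))]
  best_pos <- -1L; best_term <- NA_character_
  for (tm in terms) {
    p <- find_bounded(norm, tm)
    if (p > 0 && (best_pos < 0 || p < best_pos)) {
      best_pos <- p; best_term <- tm
    }
  }
  if (best_pos < 0) return(no_match)

  trigger <- NA_character_
  prefix <- substr(norm, 1L, best_pos - 1L)
  if (nzchar(prefix)) {
    for (mk in lexicon$uncertainty_markers) {
      p <- if (grepl("[a-z0-9]", mk)) find_bounded(prefix, mk)
           else as.integer(regexpr(escape_regex(mk), prefix))
      if (p > 0) {
        gap <- substr(prefix, p + nchar(mk), best_pos - 1L)
        n_tokens <- length(strsplit(trimws(gap), "\\s+")[[1]][nzchar(strsplit(trimws(gap), "\\s+")[[1]])])
        if (n_tokens <= lookback) { trigger <- mk; break }
      }
    }
  }
  structure(list(matched = TRUE, excluded = !is.na(trigger),
                 matched_term = best_term, exclusion_trigger = trigger),
            class = "term_match")
}

#' @export
print.term_match <- function(x, ...) {
  cat(sprintf("<term_match> matched=%s excluded=%s term=%s trigger=%s\n",
              x$matched, x$excluded, x$matched_term, x$exclusion_trigger))
  invisible(x)
}

#' Classify a prescription text into a COPD drug class
#'
#' Longest-variant-first, boundary-aware matching over the lexicon's drug
#' map, so combination products ("ipratropium/salbutamol", "Combivent") beat
#' their single-agent components. Text matching no variant — including
#' non-COPD-specific bronchodilators like salbutamol alone — classifies as
#' `"other"`.
#'
#' @param raw_text Prescription free text as entered.
#' @param lexicon A `copd_lexicon`.
#' @return One of `"tiotropium"`, `"ipratropium"`, `"ipratropium_salbutamol"`,
#'   `"other"`.
#' @examples
#' classify_drug("Spiriva 18 mcg inh od", default_lexicon())
#' @export
classify_drug <- function(raw_text, lexicon) {
  stopifnot(inherits(lexicon, "copd_lexicon"))
  if (length(raw_text) != 1 || is.na(raw_text)) return("other")
  norm <- squish(raw_text)
  if (!nzchar(norm)) return("other")
  variants <- names(lexicon$drugs)[order(-nchar(names(lexicon$drugs)))]
  for (v in variants) {
    if (find_bounded(norm, v) > 0) return(unname(lexicon$drugs[[v]]))
  }
  "other"
}
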