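# Phenotyping algorithms as monotone boolean trees (AND/OR) over atomic
# criteria, and the 12-algorithm validation catalog.

#' Atomic criterion constructors
#'
#' Leaves of an algorithm expression tree. `crit_cpp()` is a CPP
#' documentation mention; `crit_billing()` a billing-count criterion (see
#' [billing_criterion_met()]); `crit_drug()` a prescription-class criterion;
#' `crit_smoking()` a positive smoking history.
#'
#' @param codes,min_count,window_days As in [billing_criterion_met()].
#' @param classes,scope As in [drug_criterion_met()].
#' @return A list of class `atomic_criterion` with a human-readable `id`.
#' @name atomic_criteria
NULL

new_criterion <- function(kind, params, id) {
  structure(list(kind = kind, params = params, id = id),
            class = "atomic_criterion")
}

#' @rdname atomic_criteria
#' @export
crit_cpp <- function() new_criterion("cpp_mention", list(), "cpp_mention")

#' @rdname atomic_criteria
#' @export
crit_billing <- function(codes = COPD_BILLING_CODES, min_count = 1L,
                         window_days = "ever") {
  stopifnot(min_count >= 1)
  if (!identical(window_days, "ever")) stopifnot(window_days > 0)
  id <- sprintf("billing[%s]>=%d/%s", paste(codes, collapse = ","),
                min_count,
                if (identical(window_days, "ever")) "ever" else paste0(window_days, "d"))
  new_criterion("billing_count",
                list(codes = codes, min_count = as.integer(min_count),
                     window_days = window_days), id)
}

#' @rdname atomic_criteria
#' @export
crit_drug <- function(classes, scope = "ever") {
  stopifnot(all(classes %in% setdiff(DRUG_CLASSES, "other")))
  id <- sprintf("drug[%s]/%s", paste(sort(classes), collapse = ","), scope)
  new_criterion("drug_class", list(classes = classes, scope = scope), id)
}

#' @rdname atomic_criteria
#' @export
crit_smoking <- function() new_criterion("smoking_positive", list(), "smoking_positive")

#' Combine criteria or sub-expressions
#'
#' `alg_or()`/`alg_and()` build the internal nodes of an algorithm tree.
#' The catalog is monotone: no NOT nodes exist.
#'
#' @param ... `atomic_criterion` leaves or nested `alg_*` nodes.
#' @return A list of class `algorithm_node`.
#' @export
alg_or <- function(...) new_node("OR", list(...))

#' @rdname alg_or
#' @export
alg_and <- function(...) new_node("AND", list(...))

new_node <- function(op, args) {
  if (!length(args)) copd_error("algorithm node needs at least one argument",
                                "copd_validation_error")
  ok <- vapply(args, function(a) inherits(a, c("atomic_criterion", "algorithm_node")),
               logical(1))
  if (!all(ok)) copd_error("algorithm node arguments must be criteria or nodes",
                           "copd_validation_error")
  structure(list(op = op, args = args), class = "algorithm_node")
}

#' Define a named phenotyping algorithm
#'
#' @param id Algorithm identifier string.
#' @param expr An `atomic_criterion` or `algorithm_node` expression tree.
#' @return An object of class `algorithm_spec`.
#' @examples
#' spec <- algorithm_spec("cpp_only", crit_cpp())
#' @export
algorithm_spec <- function(id, expr) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (!inherits(expr, c("atomic_criterion", "algorithm_node"))) {
    copd_error("algorithm expression must be a criterion or node", "copd_validation_error")
  }
  structure(list(id = id, expr = expr), class = "algorithm_spec")
}

#' @export
print.algorithm_spec <- function(x, ...) {
  cat(sprintf("<algorithm_spec %s> %s\n", x$id, deparse_expr(x$expr)))
  invisible(x)
}

deparse_expr <- function(e) {
  if (inherits(e, "atomic_criterion")) return(e$id)
  paste0("(", paste(vapply(e$args, deparse_expr, character(1)),
                    collapse = paste0(" ", e$op, " ")), ")")
}

spec_leaves <- function(expr) {
  if (inherits(expr, "atomic_criterion")) return(list(expr))
  do.call(c, lapply(expr$args, spec_leaves))
}

eval_criterion <- function(chart, crit, lexicon, ...) {
  opts <- list(...)
  switch(crit$kind,
    cpp_mention = cpp_indicates_copd(chart, lexicon,
                                     lookback = opts$lookback %||% Inf),
    billing_count = billing_criterion_met(
      chart, crit$params$codes, crit$params$min_count, crit$params$window_days,
      dedup_same_day = isTRUE(opts$dedup_same_day),
      calendar_year = isTRUE(opts$calendar_year)),
    drug_class = drug_criterion_met(chart, crit$params$classes,
                                    crit$params$scope, lexicon),
    smoking_positive = smoking_positive(chart),
    smoking_status = {
      sm <- chart$smoking_records
      nrow(sm) > 0 &&
        sm$status[max(which(sm$date == max(sm$date)))] == crit$params$status
    },
    copd_error(sprintf("unknown criterion kind '%s'", crit$kind), "copd_internal_error")
  )
}

eval_expr <- function(expr, leaf_values) {
  if (inherits(expr, "atomic_criterion")) return(leaf_values[[expr$id]])
  vals <- vapply(expr$args, eval_expr, logical(1), leaf_values = leaf_values)
  if (expr$op == "AND") all(vals) else any(vals)
}

#' Apply a phenotyping algorithm to one chart
#'
#' Every leaf criterion is evaluated (no short-circuiting) so the audit
#' trail lists all criteria that fired, which the discordance analysis
#' relies on.
#'
#' @param chart A `patient_chart`.
#' @param spec An `algorithm_spec`.
#' @param lexicon A `copd_lexicon`.
#' @param ... Mode options forwarded to the criteria (`lookback`,
#'   `dedup_same_day`, `calendar_year`).
#' @return An `algorithm_result`: list with `patient_id`, `positive`, and
#'   `fired_criteria` (ids of all true leaves).
#' @examples
#' lex <- default_lexicon()
#' ch <- patient_chart("P1", "1950-01-01",
#'   cpp_entries = data.frame(section = "problem_list", text = "COPD"))
#' apply_algorithm(ch, catalog_algorithms()$combo_final, lex)
#' @export
apply_algorithm <- function(chart, spec, lexicon, ...) {
  stopifnot(inherits(spec, "algorithm_spec"))
  leaves <- spec_leaves(spec$expr)
  vals <- list()
  for (lf in leaves) {
    if (is.null(vals[[lf$id]])) {
      vals[[lf$id]] <- eval_criterion(chart, lf, lexicon, ...)
    }
  }
  fired <- names(vals)[vapply(vals, isTRUE, logical(1))]
  structure(list(patient_id = chart$patient_id,
                 positive = eval_expr(spec$expr, vals),
                 fired_criteria = fired),
            class = "algorithm_result")
}

#' Classify a whole cohort with one algorithm
#'
#' @param cohort List of `patient_chart` objects.
#' @param spec An `algorithm_spec`.
#' @param lexicon A `copd_lexicon`.
#' @param ... Forwarded to [apply_algorithm()].
#' @return Data frame with columns `patient_id`, `positive`,
#'   `fired_criteria` (ids collapsed with `";"`).
#' @export
classify_cohort <- function(cohort, spec, lexicon, ...) {
  res <- lapply(cohort, apply_algorithm, spec = spec, lexicon = lexicon, ...)
  data.frame(
    patient_id = vapply(res, `[[`, character(1), "patient_id"),
    positive = vapply(res, `[[`, logical(1), "positive"),
    fired_criteria = vapply(res, function(r) paste(r$fired_criteria, collapse = ";"),
                            character(1)),
    stringsAsFactors = FALSE)
}

#' The 12-algorithm validation catalog
#'
#' The frozen set of case-finding algorithms evaluated against the
#' chart-abstraction reference standard: the CPP mention alone; billing-code
#' counts (at least one ever; at least two within one year); current- and
#' ex-smoker history alone; the three prescription algorithms (any
#' COPD-specific drug, tiotropium alone, ipratropium or its combination);
#' the combination algorithm optimizing PPV and sensitivity
#' (`combo_final`: CPP, or tiotropium, or ipratropium plus at least one
#' billing code ever, or at least three billing codes within one year); the
#' higher-sensitivity alternative (`combo_alt`: CPP, or any COPD
#' prescription, or at least two billing codes within one year); and both
#' combinations augmented with a positive smoking history. Drug scope is
#' "ever" (prescribed at any point in time) throughout.
#'
#' @return Named list of 12 `algorithm_spec` objects.
#' @export
catalog_algorithms <- function() {
  ipra <- c("ipratropium", "ipratropium_salbutamol")
  any_drug <- c("tiotropium", ipra)
  combo_final <- alg_or(
    crit_cpp(),
    crit_drug("tiotropium"),
    alg_and(crit_drug(ipra), crit_billing(min_count = 1L, window_days = "ever")),
    crit_billing(min_count = 3L, window_days = 365))
  combo_alt <- alg_or(
    crit_cpp(),
    crit_drug(any_drug),
    crit_billing(min_count = 2L, window_days = 365))
  list(
    cpp_only = algorithm_spec("cpp_only", crit_cpp()),
    billing_ge1_ever = algorithm_spec("billing_ge1_ever",
                                      crit_billing(min_count = 1L, window_days = "ever")),
    billing_ge2_1yr = algorithm_spec("billing_ge2_1yr",
                                     crit_billing(min_count = 2L, window_days = 365)),
    smoker_current = algorithm_spec("smoker_current", crit_smoking_status("current")),
    smoker_ex = algorithm_spec("smoker_ex", crit_smoking_status("ex")),
    drug_tio_or_ipra = algorithm_spec("drug_tio_or_ipra", crit_drug(any_drug)),
    drug_tio = algorithm_spec("drug_tio", crit_drug("tiotropium")),
    drug_ipra = algorithm_spec("drug_ipra", crit_drug(ipra)),
    combo_final = algorithm_spec("combo_final", combo_final),
    combo_alt = algorithm_spec("combo_alt", combo_alt),
    combo_final_plus_smoking = algorithm_spec(
      "combo_final_plus_smoking", alg_or(combo_final, crit_smoking())),
    combo_alt_plus_smoking = algorithm_spec(
      "combo_alt_plus_smoking", alg_or(combo_alt, crit_smoking()))
  )
}

# most-recent smoking record has exactly this status
crit_smoking_status <- function(status) {
  new_criterion("smoking_status", list(status = status),
                sprintf("smoking_%s", status))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read algorithm definitions from a configuration file
#'
#' The file holds a map from algorithm id to a nested expression: either a
#' leaf (`{kind: billing_count, codes: [...], min_count: 2, window_days: 365}`,
#' `{kind: cpp_mention}`, `{kind: drug_class, classes: [...], scope: ever}`,
#' `{kind: smoking_positive}`) or `{and: [...]}`/`{or: [...]}` over such
#' expressions.
#'
#' @param path YAML or JSON file path.
#' @return Named list of `algorithm_spec` objects.
#' @export
read_algorithms <- function(path) {
  cfg <- read_config(path)
  if (!length(cfg)) copd_error("algorithm file defines no algorithms", "copd_parse_error")
  specs <- lapply(names(cfg), function(id) algorithm_spec(id, parse_expr_cfg(cfg[[id]])))
  names(specs) <- names(cfg)
  specs
}

parse_expr_cfg <- function(x) {
  if (!is.null(x$and)) return(do.call(alg_and, lapply(x$and, parse_expr_cfg)))
  if (!is.null(x$or)) return(do.call(alg_or, lapply(x$or, parse_expr_cfg)))
  kind <- x$kind %||% copd_error("algorithm leaf lacks 'kind'", "copd_parse_error")
  switch(kind,
    cpp_mention = crit_cpp(),
    smoking_positive = crit_smoking(),
    billing_count = crit_billing(
      codes = unlist(x$codes) %||% COPD_BILLING_CODES,
      min_count = x$min_count %||% 1L,
      window_days = if (identical(x$window_days, "ever") || is.null(x$window_days))
        "ever" else as.numeric(x$window_days)),
    drug_class = crit_drug(unlist(x$classes), scope = x$scope %||% "ever"),
    copd_error(sprintf("unknown criterion kind '%s'", kind), "copd_parse_error"))
}
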