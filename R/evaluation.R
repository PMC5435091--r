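# Diagnostic-accuracy statistics: confusion matrices against the
# chart-abstraction reference standard, exact binomial (Clopper-Pearson)
# intervals for the proportions, log-scale intervals for likelihood ratios
# and the diagnostic odds ratio, Cohen's kappa, and the validation report.

#' Construct a confusion matrix
#'
#' @param tp,tn,fp,fn Nonnegative integer cell counts (prediction vs the
#'   reference standard).
#' @return An object of class `confusion_matrix`.
#' @examples
#' confusion_matrix(tp = 280, tn = 5506, fp = 19, fn = 84)
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  cells <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    copd_error("confusion matrix cells must be nonnegative integers",
               "copd_validation_error")
  }
  structure(as.list(cells), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Tally an algorithm's predictions against the reference standard
#'
#' Reference positive means the abstraction label `"definite_copd"`; the
#' labels `"possible_copd"`, `"copd_ruled_out"` and `"no_mention"` all count
#' as reference negative (optionally, possible-COPD charts can be excluded
#' for sensitivity analysis). Every chart must carry a label and the
#' predictions must cover exactly the cohort's patient ids.
#'
#' @param results Data frame with columns `patient_id`, `positive`
#'   (as produced by [classify_cohort()]).
#' @param cohort List of labeled `patient_chart` objects.
#' @param exclude_possible Drop `"possible_copd"` charts instead of counting
#'   them as reference negatives.
#' @return A `confusion_matrix`.
#' @export
build_confusion <- function(results, cohort, exclude_possible = FALSE) {
  if (!length(cohort)) copd_error("empty cohort", "copd_evaluation_error")
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  labels <- vapply(cohort, `[[`, character(1), "reference_label")
  if (anyNA(labels)) {
    copd_error(sprintf("chart '%s' lacks reference_label; cannot evaluate",
                       ids[which(is.na(labels))[1]]), "copd_evaluation_error")
  }
  if (!setequal(results$patient_id, ids) || nrow(results) != length(ids)) {
    copd_error("results do not cover exactly the cohort patient ids",
               "copd_evaluation_error")
  }
  pred <- results$positive[match(ids, results$patient_id)]
  keep <- rep(TRUE, length(ids))
  if (exclude_possible) keep <- labels != "possible_copd"
  ref <- labels[keep] == "definite_copd"
  pred <- pred[keep]
  confusion_matrix(tp = sum(pred & ref), tn = sum(!pred & !ref),
                   fp = sum(pred & !ref), fn = sum(!pred & ref))
}

#' Proportion with an exact Clopper-Pearson interval
#'
#' The exact binomial interval in its beta-quantile formulation:
#' lower = qbeta(alpha/2; k, n-k+1), upper = qbeta(1-alpha/2; k+1, n-k),
#' with the lower bound 0 when k = 0 and the upper bound 100 when k = n.
#' Value and bounds are on the percent scale.
#'
#' @param k Number of successes, 0 <= k <= n.
#' @param n Number of trials, >= 1.
#' @param conf Confidence level (default 0.95).
#' @return A `metric_estimate`: list with `value`, `ci_low`, `ci_high`
#'   (percent) and `method = "clopper_pearson"`.
#' @examples
#' proportion_with_ci(280, 364)  # 76.9 (72.2-81.2)
#' @export
proportion_with_ci <- function(k, n, conf = 0.95) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    copd_error("proportion undefined: n must be >= 1", "copd_evaluation_error")
  }
  stopifnot(k >= 0, k <= n)
  alpha <- 1 - conf
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  metric_estimate(100 * k / n, 100 * lo, 100 * hi, "clopper_pearson")
}

metric_estimate <- function(value, ci_low, ci_high, method, corrected = FALSE) {
  structure(list(value = value, ci_low = ci_low, ci_high = ci_high,
                 method = method, corrected = corrected),
            class = "metric_estimate")
}

#' @export
print.metric_estimate <- function(x, ...) {
  cat(sprintf("%.4g (95%% CI %.4g-%.4g) [%s%s]\n", x$value, x$ci_low, x$ci_high,
              x$method, if (x$corrected) ", zero-cell corrected" else ""))
  invisible(x)
}

#' Likelihood ratios and diagnostic odds ratio with log-scale intervals
#'
#' LR+ = sens/(1-spec) and LR- = (1-sens)/spec with the Simel log-method
#' standard errors sqrt((1-sens)/TP + spec/FP) and sqrt(sens/FN +
#' (1-spec)/TN); DOR = (TP*TN)/(FP*FN) with the log-Wald (Woolf) standard
#' error sqrt(1/TP + 1/FP + 1/FN + 1/TN). When a required cell is zero the
#' Haldane-Anscombe correction (0.5 added to all four cells) is applied to
#' these ratio metrics only — never to the proportions — and the estimates
#' are flagged `corrected`.
#'
#' @param cm A `confusion_matrix`.
#' @param conf Confidence level (default 0.95).
#' @return List of `metric_estimate`s: `lr_pos`, `lr_neg`, `dor`.
#' @examples
#' ratio_metrics(confusion_matrix(280, 5506, 19, 84))
#' @export
ratio_metrics <- function(cm, conf = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  cells <- c(cm$tp, cm$tn, cm$fp, cm$fn)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  tp <- cells[1]; tn <- cells[2]; fp <- cells[3]; fn <- cells[4]
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)

  lrp <- sens / (1 - spec)
  se_lrp <- sqrt((1 - sens) / tp + spec / fp)
  lrn <- (1 - sens) / spec
  se_lrn <- sqrt(sens / fn + (1 - spec) / tn)
  dor <- (tp * tn) / (fp * fn)
  se_dor <- sqrt(1 / tp + 1 / fp + 1 / fn + 1 / tn)

  lg <- function(x, se) metric_estimate(x, exp(log(x) - z * se), exp(log(x) + z * se),
                                        "log_wald", corrected)
  list(lr_pos = lg(lrp, se_lrp), lr_neg = lg(lrn, se_lrn), dor = lg(dor, se_dor))
}

#' Predicted prevalence of an algorithm
#'
#' The proportion of the cohort the algorithm classifies positive,
#' 100*(TP+FP)/n, to compare with the reference prevalence.
#'
#' @param cm A `confusion_matrix`.
#' @param cohort_n Total cohort size; must equal the matrix total.
#' @return Percent.
#' @examples
#' predicted_prevalence(confusion_matrix(288, 5483, 42, 76), 5889)  # 5.6
#' @export
predicted_prevalence <- function(cm, cohort_n) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total != cohort_n) {
    copd_error(sprintf("confusion total %d != cohort_n %d", total, cohort_n),
               "copd_evaluation_error")
  }
  100 * (cm$tp + cm$fp) / cohort_n
}

#' Cohen's kappa for abstractor agreement
#'
#' Chance-corrected agreement between two raters over the same items:
#' kappa = (p_o - p_e)/(1 - p_e), with p_o the observed agreement and p_e
#' the agreement expected from the raters' marginal label frequencies.
#' Identical sequences give 1. When the expected agreement is 1 (both raters
#' use a single identical label throughout) kappa is undefined and `NA` is
#' returned with attribute `undefined = TRUE`.
#'
#' @param ratings_a,ratings_b Equal-length categorical label vectors.
#' @return Kappa in \[-1, 1\], or `NA` (attribute `undefined`) in the
#'   degenerate no-variability case.
#' @examples
#' cohens_kappa(c("+", "+", "-", "-"), c("+", "-", "+", "-"))  # 0
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b) || !length(ratings_a)) {
    copd_error("rating sequences must have equal, positive length",
               "copd_evaluation_error")
  }
  a <- as.character(ratings_a); b <- as.character(ratings_b)
  lev <- union(a, b)
  n <- length(a)
  po <- mean(a == b)
  pa <- table(factor(a, levels = lev)) / n
  pb <- table(factor(b, levels = lev)) / n
  pe <- sum(pa * pb)
  if (isTRUE(all.equal(pe, 1))) {
    return(structure(NA_real_, undefined = TRUE))
  }
  (po - pe) / (1 - pe)
}

#' Summarize one confusion matrix into a full metrics row
#'
#' @param cm A `confusion_matrix`.
#' @param conf Confidence level.
#' @return One-row data frame: counts, sensitivity/specificity/PPV/NPV with
#'   Clopper-Pearson bounds, LR+/LR-/DOR with log-scale bounds, predicted
#'   prevalence, and a `corrected` flag (zero-cell policy applied to the
#'   ratio metrics). All values at full precision, percent scale for
#'   proportions.
#' @export
summarize_confusion <- function(cm, conf = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  prop <- function(k, d) if (d == 0) metric_estimate(NA_real_, NA_real_, NA_real_,
                                                     "clopper_pearson")
                         else proportion_with_ci(k, d, conf)
  sens <- prop(cm$tp, cm$tp + cm$fn)
  spec <- prop(cm$tn, cm$tn + cm$fp)
  ppv <- prop(cm$tp, cm$tp + cm$fp)
  npv <- prop(cm$tn, cm$tn + cm$fn)
  rm_ <- ratio_metrics(cm, conf)
  out <- data.frame(
    tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
    sens = sens$value, sens_low = sens$ci_low, sens_high = sens$ci_high,
    spec = spec$value, spec_low = spec$ci_low, spec_high = spec$ci_high,
    ppv = ppv$value, ppv_low = ppv$ci_low, ppv_high = ppv$ci_high,
    npv = npv$value, npv_low = npv$ci_low, npv_high = npv$ci_high,
    lr_pos = rm_$lr_pos$value, lr_pos_low = rm_$lr_pos$ci_low, lr_pos_high = rm_$lr_pos$ci_high,
    lr_neg = rm_$lr_neg$value, lr_neg_low = rm_$lr_neg$ci_low, lr_neg_high = rm_$lr_neg$ci_high,
    dor = rm_$dor$value, dor_low = rm_$dor$ci_low, dor_high = rm_$dor$ci_high,
    predicted_prevalence = predicted_prevalence(cm, n),
    corrected = rm_$dor$corrected,
    stringsAsFactors = FALSE)
  out
}

#' Build the full validation report
#'
#' One row per algorithm: the confusion matrix against the reference
#' standard plus all accuracy metrics with 95% intervals and the predicted
#' prevalence. Deterministic given its inputs.
#'
#' @param cohort Labeled list of `patient_chart` objects.
#' @param specs Named list of `algorithm_spec` objects (default: the
#'   12-algorithm catalog).
#' @param lexicon A `copd_lexicon`.
#' @param conf Confidence level.
#' @param ... Mode options forwarded to [apply_algorithm()].
#' @return A data frame of class `validation_report` with an `algorithm`
#'   id column followed by the columns of [summarize_confusion()].
#' @export
build_report <- function(cohort, specs = catalog_algorithms(),
                         lexicon = default_lexicon(), conf = 0.95, ...) {
  if (!length(specs)) copd_error("need at least one algorithm", "copd_evaluation_error")
  rows <- lapply(specs, function(sp) {
    res <- classify_cohort(cohort, sp, lexicon, ...)
    cbind(data.frame(algorithm = sp$id, stringsAsFactors = FALSE),
          summarize_confusion(build_confusion(res, cohort), conf))
  })
  rep_ <- do.call(rbind, rows)
  rownames(rep_) <- NULL
  class(rep_) <- c("validation_report", "data.frame")
  rep_
}

#' Round half away from zero
#'
#' Report-display rounding (half-up), as distinct from R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

report_display_columns <- function() {
  prop_cols <- as.vector(outer(c("sens", "spec", "ppv", "npv"),
                               c("", "_low", "_high"), paste0))
  list(
    one_dp = c(prop_cols, "lr_pos", "lr_pos_low", "lr_pos_high",
               "dor", "dor_low", "dor_high", "predicted_prevalence"),
    two_dp = c("lr_neg", "lr_neg_low", "lr_neg_high"))
}

#' Apply report display rounding
#'
#' Proportions, LR+ and DOR (and their bounds) to 1 decimal; LR- to 2
#' decimals; half-up. Counts untouched.
#'
#' @param report A `validation_report`.
#' @return The report with display rounding applied.
#' @export
round_report <- function(report) {
  cols <- report_display_columns()
  for (cl in intersect(cols$one_dp, names(report))) {
    report[[cl]] <- round_half_up(report[[cl]], 1)
  }
  for (cl in intersect(cols$two_dp, names(report))) {
    report[[cl]] <- round_half_up(report[[cl]], 2)
  }
  report
}

#' Write / read a validation report as CSV
#'
#' RFC-4180 CSV mirroring the validation table layout: one row per
#' algorithm with counts, all metrics with CI bounds, and predicted
#' prevalence, at display rounding. A write-then-read round trip reproduces
#' all numbers exactly at that rounding.
#'
#' @param report A `validation_report`.
#' @param path Output (input) file path or connection.
#' @return `path` invisibly; `read_validation_report()` returns the report
#'   data frame.
#' @export
write_validation_report <- function(report, path) {
  utils::write.csv(round_report(as.data.frame(report)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_validation_report
#' @export
read_validation_report <- function(path) {
  rep_ <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(rep_) <- c("validation_report", "data.frame")
  rep_
}

#' Write a validation report as JSON keyed by algorithm id
#'
#' @param report A `validation_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  rows <- split(as.data.frame(report), report$algorithm)
  obj <- lapply(rows, function(r) as.list(r[1, setdiff(names(r), "algorithm")]))
  jsonlite::write_json(obj[unique(report$algorithm)], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
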