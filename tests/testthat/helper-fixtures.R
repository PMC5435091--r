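# Shared fixtures: chart builders, the printed validation-table rows, a
# brute-force rolling-window oracle, and a cached full-size synthetic cohort.

make_chart <- function(id = "P1", birth = "1950-01-01", ...) {
  patient_chart(patient_id = id, birth_date = birth, ...)
}

billing_df <- function(dates, codes = "496") {
  data.frame(code = rep_len(codes, length(dates)),
             date = as.character(dates), stringsAsFactors = FALSE)
}

cpp_df <- function(texts, section = "problem_list") {
  data.frame(section = rep_len(section, length(texts)), text = texts,
             date = NA_character_, stringsAsFactors = FALSE)
}

rx_df <- function(texts, status = "active", dates = "2009-05-01") {
  data.frame(raw_text = texts, date = rep_len(as.character(dates), length(texts)),
             status = rep_len(status, length(texts)), stringsAsFactors = FALSE)
}

smoking_df <- function(statuses, dates) {
  data.frame(status = statuses, date = as.character(dates),
             stringsAsFactors = FALSE)
}

# All-windows brute force: does any window of `w` consecutive days contain at
# least `m` of the qualifying day numbers? Enumerates every candidate start.
brute_force_window <- function(days, m, w) {
  if (length(days) < m) return(FALSE)
  days <- sort(days)
  starts <- seq(min(days) - w + 1, max(days))
  any(vapply(starts, function(s) sum(days >= s & days <= s + w - 1) >= m,
             logical(1)))
}

# Printed rows of the validation table that are internally consistent
# (counts reproduce their own metrics). The tiotropium and combined-
# prescription rows are inconsistent as printed and are deliberately absent.
# Two cells carry a one-print-unit discrepancy against their own counts and
# get a matching tolerance: the ipratropium DOR (prints 51.1; the counts
# give 51.0) and the ex-smoker LR- lower bound (prints 0.76; counts give
# 0.77).
table2_printed <- function() {
  row <- function(id, tp, tn, fp, fn, sens, spec, ppv, npv, lrp, lrn, dor) {
    list(id = id, tp = tp, tn = tn, fp = fp, fn = fn,
         sens = sens, spec = spec, ppv = ppv, npv = npv,
         lr_pos = lrp, lr_neg = lrn, dor = dor)
  }
  list(
    row("cpp_only", 205, 5514, 11, 159, c(56.3, 51.1, 61.5), c(99.8, 99.6, 99.9),
        c(94.9, 91.1, 97.4), c(97.2, 96.7, 97.6), c(282.9, 155.7, 514.0),
        c(0.44, 0.39, 0.49), c(646.3, 345.3, 1209.6)),
    row("billing_ge1_ever", 188, 5405, 120, 176, c(51.6, 46.4, 56.9),
        c(97.8, 97.4, 98.2), c(61.0, 55.3, 66.5), c(96.8, 96.4, 97.3),
        c(23.8, 19.4, 29.1), c(0.49, 0.44, 0.55), c(48.1, 36.6, 63.3)),
    row("billing_ge2_1yr", 100, 5510, 15, 264, c(27.5, 22.9, 32.4),
        c(99.7, 99.6, 99.8), c(87.0, 79.4, 92.5), c(95.4, 94.9, 96.0),
        c(101.2, 59.4, 172.3), c(0.73, 0.68, 0.77), c(139.1, 79.8, 242.8)),
    row("smoker_current", 102, 4971, 554, 262, c(28.0, 23.5, 32.9),
        c(90.0, 89.2, 90.8), c(15.5, 12.9, 18.6), c(95.0, 94.4, 95.6),
        c(2.8, 2.3, 3.4), c(0.80, 0.75, 0.85), c(3.5, 2.7, 4.5)),
    row("smoker_ex", 118, 4531, 994, 246, c(32.4, 27.6, 37.5),
        c(82.0, 81.0, 83.0), c(10.6, 8.9, 12.6), c(94.9, 94.2, 95.5),
        c(1.8, 1.5, 2.1), c(0.82, 0.76, 0.89), c(2.2, 1.7, 2.8)),
    row("drug_ipra", 47, 5509, 16, 317, c(12.9, 9.6, 16.8),
        c(99.7, 99.5, 99.8), c(74.6, 62.1, 84.7), c(94.6, 93.9, 95.1),
        c(44.6, 25.5, 77.8), c(0.87, 0.84, 0.91), c(51.1, 28.6, 91.0)),
    row("combo_final", 280, 5506, 19, 84, c(76.9, 72.2, 81.2),
        c(99.7, 99.5, 99.8), c(93.6, 90.3, 96.1), c(98.5, 98.1, 98.8),
        c(223.7, 142.3, 351.6), c(0.23, 0.19, 0.28), c(966.0, 578.8, 1612.1)),
    row("combo_alt", 288, 5483, 42, 76, c(79.1, 74.6, 83.2),
        c(99.2, 99.0, 99.5), c(87.3, 83.2, 90.7), c(98.6, 98.3, 98.9),
        c(104.1, 76.7, 141.3), c(0.21, 0.17, 0.26), c(494.7, 333.3, 734.4)),
    row("combo_final_plus_smoking", 325, 3969, 1556, 39, c(89.3, 85.6, 92.3),
        c(71.8, 70.6, 73.0), c(17.3, 15.6, 19.1), c(99.0, 98.7, 99.3),
        c(3.2, 3.0, 3.4), c(0.15, 0.11, 0.20), c(21.3, 15.2, 29.8)),
    row("combo_alt_plus_smoking", 329, 3955, 1570, 35, c(90.4, 86.9, 93.2),
        c(71.6, 70.4, 72.8), c(17.3, 15.6, 19.1), c(99.1, 98.8, 99.4),
        c(3.2, 3.0, 3.4), c(0.13, 0.10, 0.18), c(23.7, 16.6, 33.7))
  )
}

# cells where the printed table disagrees with its own counts by one unit in
# the last printed digit; keyed "<row id>.<metric>[<element>]"
table2_print_slack <- c(
  "drug_ipra.dor1" = 0.11,   # point value
  "smoker_ex.lr_neg2" = 0.011  # lower CI bound
)

# full-size default cohort, generated once per test run
cached_cohort_env <- new.env(parent = emptyenv())
default_cohort_fixture <- function() {
  if (is.null(cached_cohort_env$cohort)) {
    p <- default_params()
    p$seed <- 20170515L
    cached_cohort_env$cohort <- generate_cohort(p)
  }
  cached_cohort_env$cohort
}

label_of <- function(chart) chart$reference_label

copd_count <- function(cohort) {
  sum(vapply(cohort, function(ch) identical(ch$reference_label, "definite_copd"),
             logical(1)))
}
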