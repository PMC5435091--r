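test_that("generation is deterministic given the seed and leaves the RNG alone", {
  p <- default_params(); p$n <- 150L; p$seed <- 33L
  set.seed(999); before <- stats::runif(3)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a, b)
  set.seed(999); expect_identical(stats::runif(3), before)
  p2 <- p; p2$seed <- 34L
  expect_false(identical(generate_cohort(p2), a))
})

test_that("prevalence bounds are honored at the extremes", {
  p <- default_params(); p$n <- 80L; p$seed <- 5L
  p$prevalence <- 0
  expect_identical(copd_count(generate_cohort(p)), 0L)
  p$prevalence <- 1
  expect_identical(copd_count(generate_cohort(p)), 80L)
})

test_that("generated charts satisfy the data-model invariants", {
  p <- default_params(); p$n <- 300L; p$seed <- 8L
  cohort <- generate_cohort(p)
  index <- as.Date("2010-12-31")
  ids <- vapply(cohort, function(c) c$patient_id, character(1))
  expect_false(any(duplicated(ids)))
  for (ch in cohort) {
    expect_true(chart_age(ch, index) >= 35)
    for (fld in c("billing_events", "prescriptions", "smoking_records")) {
      d <- ch[[fld]]$date
      expect_true(all(is.na(d) | (d >= ch$birth_date & d <= index)))
    }
    expect_true(ch$reference_label %in%
                  c("definite_copd", "possible_copd", "copd_ruled_out", "no_mention"))
  }
  # round-trip through the interchange format preserves everything
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_charts(cohort, path)
  expect_identical(read_charts(path), cohort)
})

test_that("billing tiers are realized literally in event placement", {
  p <- default_params(); p$n <- 600L; p$seed <- 13L
  # exaggerate tier mass so every tier is exercised
  p$copd$p_billing_ge1 <- 0.9; p$copd$p_billing_ge2_1yr <- 0.6
  p$copd$p_billing_ge3_1yr <- 0.3; p$prevalence <- 0.5
  cohort <- generate_cohort(p)
  codes <- c("491", "492", "496")
  for (ch in cohort) {
    ge3 <- billing_criterion_met(ch, codes, 3, 365)
    ge2 <- billing_criterion_met(ch, codes, 2, 365)
    ge1 <- billing_criterion_met(ch, codes, 1, "ever")
    if (ge3) expect_true(ge2)
    if (ge2) expect_true(ge1)
  }
})

test_that("conditional feature rates are recovered within three standard errors", {
  cohort <- default_cohort_fixture()  # n = 5889, fixed seed
  p <- default_params()
  is_copd <- vapply(cohort, function(c) identical(c$reference_label, "definite_copd"),
                    logical(1))
  n_pos <- sum(is_copd)
  # label prevalence itself, per the binomial SE
  expect_lt(abs(n_pos - p$n * p$prevalence),
            3 * sqrt(p$n * p$prevalence * (1 - p$prevalence)) + 1e-9)

  lex <- default_lexicon()
  codes <- c("491", "492", "496")
  feats <- list(
    p_cpp_doc = function(ch) any(vapply(ch$cpp_entries$text, function(tx)
      match_copd_term(tx, lex)$matched, logical(1))),
    p_billing_ge1 = function(ch) billing_criterion_met(ch, codes, 1, "ever"),
    p_billing_ge2_1yr = function(ch) billing_criterion_met(ch, codes, 2, 365),
    p_billing_ge3_1yr = function(ch) billing_criterion_met(ch, codes, 3, 365),
    p_tiotropium = function(ch) drug_criterion_met(ch, "tiotropium", "ever", lex),
    p_ipratropium = function(ch) drug_criterion_met(
      ch, c("ipratropium", "ipratropium_salbutamol"), "ever", lex),
    p_smoking_recorded = function(ch) nrow(ch$smoking_records) > 0,
    p_pft = function(ch) ch$pft_on_chart,
    p_female = function(ch) ch$sex == "female")
  for (side in c("copd", "non_copd")) {
    sel <- if (side == "copd") is_copd else !is_copd
    m <- sum(sel)
    for (nm in names(feats)) {
      target <- p[[side]][[nm]]
      emp <- mean(vapply(cohort[sel], feats[[nm]], logical(1)))
      se <- sqrt(max(target * (1 - target), 1e-12) / m)
      expect_lt(abs(emp - target), 3 * se + 1e-9,
                label = sprintf("%s.%s emp=%.4f target=%.4f", side, nm, emp, target))
    }
  }
})

test_that("the classification pipeline closes over the generator's rates", {
  cohort <- default_cohort_fixture()
  p <- default_params()
  lex <- default_lexicon()
  rep_ <- build_report(cohort, catalog_algorithms()["cpp_only"], lex)
  n_pos <- rep_$tp + rep_$fn
  n_neg <- rep_$tn + rep_$fp
  sens_expect <- 100 * p$copd$p_cpp_doc * (1 - p$copd$p_cpp_excluded_phrasing)
  spec_expect <- 100 * (1 - p$non_copd$p_cpp_doc)
  expect_lt(abs(rep_$sens - sens_expect),
            300 * sqrt(sens_expect / 100 * (1 - sens_expect / 100) / n_pos) + 1e-9)
  expect_lt(abs(rep_$spec - spec_expect),
            300 * sqrt(spec_expect / 100 * (1 - spec_expect / 100) / n_neg) + 1e-9)
})

test_that("the dependence knob concentrates documentation without moving marginals far", {
  p <- default_params(); p$n <- 1200L; p$seed <- 21L; p$dependence <- 0.8
  cohort <- generate_cohort(p)
  lex <- default_lexicon()
  is_copd <- vapply(cohort, function(c) identical(c$reference_label, "definite_copd"),
                    logical(1))
  doc_cpp <- vapply(cohort, function(ch) any(vapply(
    ch$cpp_entries$text, function(tx) match_copd_term(tx, lex)$matched,
    logical(1))), logical(1))
  doc_bill <- vapply(cohort, function(ch)
    billing_criterion_met(ch, c("491", "492", "496"), 1, "ever"), logical(1))
  # among COPD cases, the latent completeness variable induces a positive
  # association between the two documentation channels
  tab <- table(doc_cpp[is_copd], doc_bill[is_copd])
  if (all(dim(tab) == c(2, 2)) && all(tab > 0)) {
    or_ <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    expect_gt(or_, 1)
  }
})

test_that("invalid parameters are rejected", {
  p <- default_params()
  expect_error(cohort_params(0, 0.1, 1, 0, p$copd, p$non_copd))
  expect_error(cohort_params(10, 1.5, 1, 0, p$copd, p$non_copd),
               class = "copd_validation_error")
  bad <- p$copd; bad$p_billing_ge3_1yr <- 0.9
  expect_error(cohort_params(10, 0.1, 1, 0, bad, p$non_copd),
               "nested", class = "copd_validation_error")
})

test_that("cohort parameters load from config with defaults filled in", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n = 40, prevalence = 0.25, seed = 3,
                        copd = list(p_tiotropium = 0.9)), path)
  p <- read_cohort_params(path)
  expect_identical(p$n, 40L)
  expect_equal(p$copd$p_tiotropium, 0.9)
  expect_equal(p$non_copd$p_pft, default_params()$non_copd$p_pft)
  cohort <- generate_cohort(p)
  expect_length(cohort, 40L)
})
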