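lex <- default_lexicon()
codes <- c("491", "492", "496")

test_that("CPP documentation requires a non-excluded term match", {
  expect_true(cpp_indicates_copd(
    make_chart(cpp_entries = cpp_df("COPD — stable")), lex))
  expect_false(cpp_indicates_copd(make_chart(cpp_entries = cpp_df("?COPD")), lex))
  expect_false(cpp_indicates_copd(make_chart(), lex))
  # one excluded and one clean entry: the clean entry decides
  expect_true(cpp_indicates_copd(
    make_chart(cpp_entries = cpp_df(c("?COPD", "COPD"))), lex))
})

test_that("billing criterion handles 'ever' and rolling windows", {
  d0 <- as.Date("2005-01-10")
  ch3 <- make_chart(billing_events = billing_df(d0 + c(0, 100, 200),
                                                c("496", "491", "492")))
  expect_true(billing_criterion_met(ch3, codes, 3, 365))
  ch_spread <- make_chart(billing_events = billing_df(d0 + c(0, 200, 400)))
  expect_false(billing_criterion_met(ch_spread, codes, 3, 365))
  expect_true(billing_criterion_met(ch_spread, codes, 3, "ever"))
  expect_true(billing_criterion_met(
    make_chart(billing_events = billing_df("1999-03-01", "491")), codes, 1, "ever"))
  expect_false(billing_criterion_met(
    make_chart(billing_events = billing_df(d0 + 0:3, "786")), codes, 1, "ever"))
  # subcoded claims count toward the 3-digit stem
  expect_true(billing_criterion_met(
    make_chart(billing_events = billing_df(d0, "491.2")), codes, 1, "ever"))
})

test_that("window endpoints are inclusive on both sides", {
  d0 <- as.Date("2005-01-10")
  ch <- make_chart(billing_events = billing_df(d0 + c(0, 364)))
  expect_true(billing_criterion_met(ch, codes, 2, 365))
  ch2 <- make_chart(billing_events = billing_df(d0 + c(0, 365)))
  expect_false(billing_criterion_met(ch2, codes, 2, 365))
})

test_that("rolling-window counting agrees with the all-windows brute force", {
  set.seed(101)
  for (i in 1:300) {
    k <- sample(0:8, 1)
    days <- sort(sample(0:1200, k, replace = TRUE))
    m <- sample(1:4, 1)
    w <- sample(c(30, 90, 365, 400), 1)
    ch <- make_chart(billing_events =
                       if (k) billing_df(as.Date("2004-01-01") + days) else NULL)
    expect_identical(billing_criterion_met(ch, codes, m, w),
                     brute_force_window(days, m, w),
                     label = sprintf("days=%s m=%d w=%d",
                                     paste(days, collapse = ","), m, w))
  }
})

test_that("a window at least as long as the chart span equals 'ever'", {
  set.seed(202)
  for (i in 1:50) {
    days <- sort(sample(0:1500, sample(1:6, 1)))
    ch <- make_chart(billing_events = billing_df(as.Date("2004-01-01") + days))
    m <- sample(1:4, 1)
    span <- diff(range(days)) + 1
    expect_identical(billing_criterion_met(ch, codes, m, span),
                     billing_criterion_met(ch, codes, m, "ever"))
  }
})

test_that("same-day duplicate claims count per record unless de-duplicated", {
  ch <- make_chart(billing_events = billing_df(rep("2005-01-10", 3)))
  expect_true(billing_criterion_met(ch, codes, 3, 365))
  expect_false(billing_criterion_met(ch, codes, 3, 365, dedup_same_day = TRUE))
})

test_that("calendar-year mode groups by calendar year, not rolling windows", {
  ch <- make_chart(billing_events = billing_df(c("2005-12-01", "2006-01-15")))
  expect_true(billing_criterion_met(ch, codes, 2, 365))
  expect_false(billing_criterion_met(ch, codes, 2, 365, calendar_year = TRUE))
})

test_that("drug criterion honors class sets and prescription scope", {
  tio_old <- make_chart(prescriptions = rx_df("Spiriva 18 mcg", status = "inactive",
                                              dates = "2004-01-01"))
  expect_true(drug_criterion_met(tio_old, "tiotropium", "ever", lex))
  expect_false(drug_criterion_met(tio_old, "tiotropium", "active", lex))
  ipra_only <- make_chart(prescriptions = rx_df("Atrovent 20 mcg"))
  expect_false(drug_criterion_met(ipra_only, "tiotropium", "ever", lex))
  expect_true(drug_criterion_met(ipra_only,
                                 c("ipratropium", "ipratropium_salbutamol"),
                                 "ever", lex))
  expect_false(drug_criterion_met(make_chart(), "tiotropium", "ever", lex))
})

test_that("smoking status is governed by the most recent record", {
  expect_true(smoking_positive(
    make_chart(smoking_records = smoking_df(c("non", "current"),
                                            c("2010-01-01", "2012-01-01")))))
  expect_false(smoking_positive(
    make_chart(smoking_records = smoking_df(c("current", "non"),
                                            c("2010-01-01", "2012-01-01")))))
  expect_false(smoking_positive(make_chart()))
  expect_false(smoking_positive(
    make_chart(smoking_records = smoking_df("unspecified", "2012-01-01"))))
  # date tie: later record in chart order wins
  expect_true(smoking_positive(
    make_chart(smoking_records = smoking_df(c("non", "ex"),
                                            c("2012-01-01", "2012-01-01")))))
  expect_false(smoking_positive(
    make_chart(smoking_records = smoking_df(c("ex", "non"),
                                            c("2012-01-01", "2012-01-01")))))
})

test_that("adding qualifying evidence never turns an atomic criterion false", {
  set.seed(303)
  base_charts <- lapply(1:40, function(i) {
    k <- sample(0:4, 1)
    make_chart(
      cpp_entries = if (sample(c(TRUE, FALSE), 1)) cpp_df(sample(
        c("COPD", "?COPD", "hypertension"), 1)) else NULL,
      billing_events = if (k) billing_df(
        as.Date("2005-01-01") + sample(0:900, k, replace = TRUE)) else NULL,
      prescriptions = if (sample(c(TRUE, FALSE), 1)) rx_df("Atrovent") else NULL)
  })
  augment <- function(ch) {
    ch$billing_events <- rbind(ch$billing_events, data.frame(
      code = "491", date = as.Date("2005-06-01"), stringsAsFactors = FALSE))
    ch$prescriptions <- rbind(ch$prescriptions, data.frame(
      raw_text = "Spiriva 18", date = as.Date("2009-05-01"), status = "active",
      stringsAsFactors = FALSE))
    ch$cpp_entries <- rbind(ch$cpp_entries, data.frame(
      section = "problem_list", text = "COPD", date = as.Date(NA),
      stringsAsFactors = FALSE))
    ch
  }
  for (ch in base_charts) {
    aug <- augment(ch)
    for (crit in list(
      function(x) cpp_indicates_copd(x, lex),
      function(x) billing_criterion_met(x, codes, 2, 365),
      function(x) billing_criterion_met(x, codes, 1, "ever"),
      function(x) drug_criterion_met(x, "tiotropium", "ever", lex))) {
      expect_false(crit(ch) && !crit(aug))
    }
  }
})
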