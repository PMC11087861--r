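test_that("ISI totals and clinical bands score correctly", {
  expect_equal(score_isi(rep(0, 7))$total, 0L)
  expect_equal(as.character(score_isi(rep(0, 7))$band), "none")
  expect_equal(score_isi(rep(4, 7))$total, 28L)
  expect_equal(as.character(score_isi(rep(4, 7))$band), "severe")
  s <- score_isi(c(3, 3, 2, 3, 3, 2, 2))
  expect_equal(s$total, 18L)
  expect_equal(as.character(s$band), "moderate")
  # band boundary: 14 is mild, 15 moderate
  expect_equal(as.character(isi_band(14)), "mild")
  expect_equal(as.character(isi_band(15)), "moderate")
  expect_error(score_isi(rep(2, 6)), class = "dcbti_invalid_response")
  expect_error(score_isi(c(rep(2, 6), 5)), class = "dcbti_invalid_response")
  expect_error(score_isi(c(rep(2, 6), NA)), class = "dcbti_invalid_response")
  expect_error(score_isi(c(rep(2, 6), 1.5)), class = "dcbti_invalid_response")
})

test_that("the ISI band map is a monotone partition of 0-28", {
  bands <- isi_band(0:28)
  expect_length(bands, 29)
  expect_false(anyNA(bands))
  # monotone: band index never decreases with the total
  expect_true(all(diff(as.integer(bands)) >= 0))
  # frozen boundaries
  expect_equal(as.character(bands[c(1, 8, 9, 15, 16, 22, 23, 29)]),
               c("none", "none", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
  expect_error(isi_band(29), class = "dcbti_invalid_response")
})

test_that("ISI scoring equals the brute-force sum on random responses", {
  set.seed(404)
  for (i in 1:300) {
    items <- sample(0:4, 7, replace = TRUE)
    expect_equal(score_isi(items)$total, oracle_sum(items))
  }
})

test_that("DBAS-16 totals, ranking and belief prioritization", {
  expect_equal(score_dbas(rep(0, 16))$total, 0)
  expect_equal(score_dbas(rep(5, 16))$total, 80)
  items <- (1:16) %% 4
  expect_equal(score_dbas(items)$total, oracle_sum(items))
  expect_error(score_dbas(rep(5, 15)), class = "dcbti_invalid_response")
  expect_error(score_dbas(rep(11, 16)), class = "dcbti_invalid_response")
  # configurable scale
  expect_equal(score_dbas(rep(4, 16), scale_max = 4)$total, 64)

  # one dominant item comes first
  v <- rep(0, 16); v[7] <- 10
  expect_equal(top_dysfunctional_beliefs(score_dbas(v))[1], 7L)
  # full tie -> items 1, 2, 3
  expect_equal(top_dysfunctional_beliefs(score_dbas(rep(6, 16))), 1:3)
  # ties broken by ascending index: two 9s then the 8
  w <- c(9, 9, 8, 7, rep(1, 12))
  expect_equal(top_dysfunctional_beliefs(score_dbas(w)), c(1L, 2L, 3L))
  w2 <- c(1, 9, 3, 9, 8, rep(1, 11))
  expect_equal(top_dysfunctional_beliefs(score_dbas(w2)), c(2L, 4L, 5L))
  expect_error(top_dysfunctional_beliefs(score_dbas(w), k = 17),
               class = "dcbti_invalid_response")
})

test_that("sleep-needs level uses the item mean with a high-at-cutoff boundary", {
  expect_equal(score_sleep_needs(rep(0, 4)), "low")
  expect_equal(score_sleep_needs(rep(4, 4)), "high")
  # mean exactly at the cutoff is high
  expect_equal(score_sleep_needs(c(1, 2, 1, 2)), "high")
  expect_equal(score_sleep_needs(c(1, 2, 1, 1)), "low")
  expect_equal(score_sleep_needs(c(1, 2, 1, 2), cutoff = 2), "low")
  expect_error(score_sleep_needs(c(1, 2, 1)), class = "dcbti_invalid_response")
})

test_that("eligibility screen applies every inclusion and exclusion rule", {
  good <- screening_form(age_years = 54, months_since_treatment = 12,
                         sleep_problem_nights_per_week = 4,
                         sleep_problem_duration_months = 6)
  expect_true(screen_eligibility(good)$eligible)

  apnea <- screening_form(age_years = 54, months_since_treatment = 12,
                          sleep_problem_nights_per_week = 4,
                          sleep_problem_duration_months = 6,
                          apnea_symptom_count = 3)
  d <- screen_eligibility(apnea)
  expect_false(d$eligible)
  expect_match(d$reasons, "sleep apnea", all = FALSE)

  # > 5 years since treatment
  stale <- screening_form(age_years = 54, months_since_treatment = 72,
                          sleep_problem_nights_per_week = 4,
                          sleep_problem_duration_months = 6)
  expect_false(screen_eligibility(stale)$eligible)

  # every failed rule is listed
  multi <- screening_form(age_years = 17, months_since_treatment = 1,
                          sleep_problem_nights_per_week = 1,
                          sleep_problem_duration_months = 1,
                          night_shift = TRUE)
  expect_length(screen_eligibility(multi)$reasons, 5)
})

test_that("any single exclusion flag makes the decision ineligible", {
  flags <- c("other_sleep_disorder", "insomnia_before_cancer",
             "interfering_physical_symptoms", "other_major_condition",
             "active_cancer", "prior_cbti", "night_shift")
  for (fl in flags) {
    args <- list(age_years = 54, months_since_treatment = 12,
                 sleep_problem_nights_per_week = 4,
                 sleep_problem_duration_months = 6)
    args[[fl]] <- TRUE
    d <- screen_eligibility(do.call(screening_form, args))
    expect_false(d$eligible)
    expect_length(d$reasons, 1)
  }
})

test_that("instrument CSVs score row-wise with validation", {
  df <- data.frame(participant_id = c("P01", "P02"),
                   timepoint = "baseline")
  for (j in 1:7) df[[paste0("item", j)]] <- c(3, 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  out <- score_instrument_csv(f, "isi")
  expect_equal(out$total, c(21, 7))
  expect_equal(out$band, c("moderate", "none"))

  df$item7 <- c(3, 9)  # out of range on file line 3
  write.csv(df, f, row.names = FALSE)
  expect_error(score_instrument_csv(f, "isi"), "line 3",
               class = "dcbti_invalid_response")
})
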