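# Engagement matrix with a given number of adherent participants per week.
adherent_matrix <- function(counts, n = 30) {
  m <- matrix(0L, n, 7)
  for (w in seq_along(counts)) {
    if (counts[w] > 0) m[seq_len(counts[w]), w] <- 7L
  }
  m
}

test_that("weekly and overall adherence reproduce the percentage convention", {
  # 29 of 30 adherent -> 97%
  a <- weekly_adherence(adherent_matrix(c(29, 29, 30, 30, 30, 30, 29)), 30)
  expect_equal(a$weekly_pct, c(97L, 97L, 100L, 100L, 100L, 100L, 97L))
  # overall is the mean of the unrounded weekly rates: 690/7 -> 99%
  expect_equal(a$overall_pct, 99L)
  expect_true(a$acceptable)

  full <- weekly_adherence(matrix(7L, 30, 7), 30)
  expect_equal(full$weekly_pct, rep(100L, 7))
  expect_equal(full$overall_pct, 100L)
  expect_true(full$acceptable)

  # 3 engaged days miss the 4-day bar
  some <- weekly_adherence(matrix(3L, 30, 7), 30)
  expect_equal(some$overall_pct, 0L)
  expect_false(some$acceptable)

  expect_error(weekly_adherence(matrix(7L, 30, 7), 0),
               class = "dcbti_config_error")
})

test_that("adherence accepts long data frames and ignores participant order", {
  df <- data.frame(participant_id = rep(c("B", "A"), each = 7),
                   week = rep(1:7, 2), days_active = 7L)
  df$days_active[df$participant_id == "B" & df$week == 2] <- 1L
  a <- weekly_adherence(df, 2)
  expect_equal(a$weekly_pct[2], 50L)
  b <- weekly_adherence(df[sample(nrow(df)), ], 2)
  expect_equal(a$weekly_pct, b$weekly_pct)
})

test_that("engagement logs map dates to protocol weeks per enrollment", {
  eng <- data.frame(
    participant_id = c("P1", "P1", "P1", "P2"),
    date = c("2022-01-03", "2022-01-09", "2022-01-10", "2022-01-12"))
  m <- engagement_days_matrix(eng, as.Date("2022-01-03"),
                              ids = c("P1", "P2"))
  expect_equal(unname(m["P1", 1]), 2L)  # days 0 and 6 fall in week 1
  expect_equal(unname(m["P1", 2]), 1L)  # day 7 starts week 2
  expect_equal(unname(m["P2", 2]), 1L)
  # duplicate same-day interactions count once
  eng2 <- rbind(eng, eng[1, ])
  expect_equal(engagement_days_matrix(eng2, as.Date("2022-01-03"),
                                      ids = c("P1", "P2")), m)
  expect_error(
    engagement_days_matrix(data.frame(participant_id = "P1",
                                      date = "2022-03-01"),
                           as.Date("2022-01-03")),
    class = "dcbti_invalid_entry")
})

test_that("attrition rate and feasibility verdict", {
  a <- attrition_rate(rep(TRUE, 30))
  expect_equal(a$attrition_pct, 0)
  expect_true(a$feasible)
  expect_false(attrition_rate(rep(FALSE, 30))$feasible)
  expect_equal(attrition_rate(rep(FALSE, 30))$attrition_pct, 100)
  # 8 of 30 withdrawn -> 26.7%, above the 25% bound
  b <- attrition_rate(c(rep(FALSE, 8), rep(TRUE, 22)))
  expect_equal(b$attrition_pct, 26.7)
  expect_false(b$feasible)
  # participant order is irrelevant
  expect_equal(attrition_rate(sample(c(rep(FALSE, 8), rep(TRUE, 22)))),
               b)
})

test_that("acceptability proportions and verdicts", {
  n <- 30
  useful <- matrix(1L, n, 10)
  useful[1:24, 3] <- 3L  # 24/30 rate feature 3 at least a little useful
  sat <- c(rep(5, 27), rep(2, 3))       # 27/30 satisfied
  rec <- c(rep(4, 28), rep(1, 2))
  a <- acceptability_summary(useful, sat, rec)
  expect_equal(a$feature_useful_pct[3], 80)
  expect_equal(a$any_feature_useful_pct, 80)
  expect_true(a$usefulness_acceptable)
  expect_equal(a$satisfaction_pct, 90)
  expect_true(a$satisfaction_acceptable)
  expect_equal(a$recommend_pct, 93)

  # all ratings at scale minimum: everything 0 and failing
  z <- acceptability_summary(matrix(1L, n, 10), rep(1, n), rep(1, n))
  expect_equal(z$any_feature_useful_pct, 0)
  expect_false(z$usefulness_acceptable)
  expect_false(z$satisfaction_acceptable)

  # stricter cutoff: "at least moderately useful"
  a3 <- acceptability_summary(useful, sat, rec, usefulness_cutoff = 3)
  expect_equal(a3$feature_useful_pct[3], 80)
  expect_error(acceptability_summary(matrix(5L, 3, 10), rep(5, 3), rep(5, 3)),
               class = "dcbti_invalid_response")
})

test_that("change statistics compute both Cohen's d standardizations", {
  # summary input: only the pooled variant is available
  cs <- change_statistics(list(mean = 18.5, sd = 4.6, n = 30),
                          list(mean = 10.4, sd = 4.2, n = 30))
  expect_equal(cs$mean_change, 8.1)
  expect_equal(cs$d_pooled, 8.1 / sqrt((4.6^2 + 4.2^2) / 2))
  expect_false(cs$d_change_available)
  expect_true(is.na(cs$d_change))

  dbas <- change_statistics(list(mean = 47, sd = 10.8, n = 30),
                            list(mean = 36, sd = 12.7, n = 30))
  expect_equal(dbas$mean_change, 11)

  # identical paired vectors: zero change, zero d
  x <- c(10, 12, 14, 16)
  same <- change_statistics(x, x)
  expect_equal(same$mean_change, 0)
  expect_equal(same$d_pooled, 0)
  expect_equal(same$d_change, 0)

  # raw paired vectors yield the change-score variant
  set.seed(505)
  b <- rnorm(20, 18, 4)
  f <- b - rnorm(20, 8, 3)
  cs2 <- change_statistics(b, f)
  expect_true(cs2$d_change_available)
  expect_equal(cs2$d_change, mean(b - f) / sd(b - f))

  expect_error(change_statistics(1:5, 1:4, paired = TRUE),
               class = "dcbti_invalid_response")
})

test_that("pooled d is antisymmetric under exchanging timepoints", {
  set.seed(606)
  for (i in 1:20) {
    b <- rnorm(15, 20, 5)
    f <- rnorm(15, 12, 4)
    expect_equal(change_statistics(b, f)$d_pooled,
                 -change_statistics(f, b)$d_pooled)
  }
})

test_that("medication comparisons report proportions and tests", {
  rx <- medication_use_comparison(30, 7, 1)
  expect_equal(rx$baseline_pct, 23)
  expect_equal(rx$followup_pct, 3)
  expect_equal(rx$method, "chi2")
  expect_true(rx$p_value >= 0 && rx$p_value <= 1)

  otc <- medication_use_comparison(30, 14, 9)
  expect_equal(otc$baseline_pct, 47)
  expect_equal(otc$followup_pct, 30)

  # identical counts: no association, chi-square 0, p 1
  same <- medication_use_comparison(30, 9, 9)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # the chi-square route matches stats::chisq.test on the 2x2 directly
  ct <- suppressWarnings(stats::chisq.test(
    rbind(c(7, 23), c(1, 29)), correct = FALSE))
  expect_equal(rx$statistic, unname(ct$statistic))
  expect_equal(rx$p_value, ct$p.value)

  # McNemar needs discordant counts
  mc0 <- medication_use_comparison(30, 7, 1, method = "mcnemar")
  expect_false(mc0$available)
  expect_true(is.na(mc0$p_value))
  mc <- medication_use_comparison(30, 7, 1, discordant = c(6, 0),
                                  method = "mcnemar")
  expect_true(mc$available)
  expect_true(mc$p_value >= 0 && mc$p_value <= 1)
  expect_error(medication_use_comparison(30, 7, 1, discordant = c(2, 0),
                                         method = "mcnemar"),
               class = "dcbti_invalid_response")
  expect_error(medication_use_comparison(30, 31, 1),
               class = "dcbti_invalid_response")
})

test_that("ISI band tables count and percentage both timepoints", {
  baseline <- c(rep(10, 5), rep(18, 19), rep(24, 6))
  week7 <- c(rep(5, 8), rep(10, 18), rep(16, 4))
  tab <- isi_band_table(baseline, week7)
  expect_equal(tab$baseline_n, c(0L, 5L, 19L, 6L))
  expect_equal(tab$baseline_pct, c(0L, 17L, 63L, 20L))
  expect_equal(tab$week7_n, c(8L, 18L, 4L, 0L))
  expect_equal(tab$week7_pct, c(27L, 60L, 13L, 0L))

  all_zero <- isi_band_table(rep(0, 12), rep(0, 12))
  expect_equal(all_zero$baseline_pct, c(100L, 0L, 0L, 0L))
})

test_that("score correlation is Pearson and rejects degenerate input", {
  x <- c(2, 5, 9, 11, 20)
  expect_equal(score_correlation(x, 2 * x + 1), 1)
  expect_equal(score_correlation(x, -x), -1)
  y <- c(3, 1, 7, 6, 2)
  expect_equal(score_correlation(x, y), oracle_pearson(x, y))
  expect_error(score_correlation(x, rep(4, 5)), class = "dcbti_degenerate")
  expect_error(score_correlation(1:2, 1:2), class = "dcbti_invalid_response")
})
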