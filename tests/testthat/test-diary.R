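test_that("nightly metrics match the minute-enumeration oracle", {
  cases <- list(
    # bed, try, sol, waso, final, out
    list("23:00", "23:00", 30, 30, "07:00", "07:00"),
    list("23:30", "23:30", 0, 0, "06:30", "06:30"),   # midnight wrap
    list("22:00", "22:30", 60, 45, "06:00", "07:00"),
    list("21:45", "22:00", 12, 7, "05:30", "06:15"),
    list("00:15", "00:20", 5, 0, "07:40", "07:45")
  )
  for (cs in cases) {
    e <- diary_entry("P01", "2022-01-10", cs[[1]], cs[[2]], cs[[3]], 1,
                     cs[[4]], cs[[5]], cs[[6]])
    m <- derive_entry_metrics(e)
    o <- oracle_night(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]], cs[[6]])
    expect_equal(m$tib_min, o$tib)
    expect_equal(m$tst_min, o$tst)
    expect_equal(m$sleep_efficiency_pct, o$se)
  }
  # frozen values for the canonical cases
  m1 <- derive_entry_metrics(diary_entry("P01", "2022-01-10", "23:00",
                                         "23:00", 30, 2, 30, "07:00",
                                         "07:00"))
  expect_equal(unclass(m1)[c("tib_min", "tst_min", "sleep_efficiency_pct")],
               list(tib_min = 480L, tst_min = 420L,
                    sleep_efficiency_pct = 87.5))
  m2 <- derive_entry_metrics(diary_entry("P01", "2022-01-10", "23:30",
                                         "23:30", 0, 0, 0, "06:30", "06:30"))
  expect_equal(m2$sleep_efficiency_pct, 100.0)
  m3 <- derive_entry_metrics(diary_entry("P01", "2022-01-10", "22:00",
                                         "22:30", 60, 2, 45, "06:00",
                                         "07:00"))
  expect_equal(unclass(m3)[c("tib_min", "tst_min", "sleep_efficiency_pct")],
               list(tib_min = 540L, tst_min = 345L,
                    sleep_efficiency_pct = 63.9))
})

test_that("invalid nights are rejected with the offending field named", {
  # zero time in bed
  expect_error(diary_entry("P01", "2022-01-10", "23:00", "23:00", 0, 0, 0,
                           "23:00", "23:00"),
               "time in bed is zero", class = "dcbti_invalid_entry")
  # wakefulness exceeding time in bed
  expect_error(diary_entry("P01", "2022-01-10", "23:00", "23:00", 400, 0,
                           200, "07:00", "07:00"),
               "exceeds time in bed", class = "dcbti_invalid_entry")
  # a 20-hour bed interval is a data error
  expect_error(diary_entry("P01", "2022-01-10", "10:00", "10:00", 0, 0, 0,
                           "06:00", "06:00"),
               "18 h", class = "dcbti_invalid_entry")
  expect_error(diary_entry("P01", "2022-01-10", "23:00", "23:00", -5, 0, 0,
                           "07:00", "07:00"),
               class = "dcbti_invalid_entry")
})

test_that("weekly aggregation pools minutes and flags sparse weeks", {
  wk <- aggregate_week(make_identical_week(), week_index = 1)
  expect_false(wk$insufficient)
  expect_equal(wk$sleep_efficiency_pct, 87.5)
  expect_equal(wk$bedtime_consistency_min, 0)
  expect_equal(wk$wake_consistency_min, 0)
  expect_equal(wk$avg_bedtime, parse_clock("23:00"))
  expect_equal(wk$avg_awakenings, 2)

  # 2 logged nights with min_days 3 -> insufficient
  expect_true(aggregate_week(make_identical_week(2))$insufficient)
  # empty week is an insufficient-data result, not an error
  empty <- aggregate_week(list())
  expect_true(empty$insufficient)
  expect_equal(empty$days_logged, 0)
  expect_true(is.na(empty$sleep_efficiency_pct))

  # pooled SE: TST {420,400,440} over TIB {480,480,480} = 1260/1440
  mk <- function(sol) diary_entry("P01", "2022-01-10", "23:00", "23:00",
                                  sol, 1, 0, "07:00", "07:00")
  wk3 <- aggregate_week(list(mk(60), mk(80), mk(40)))
  expect_equal(wk3$sleep_efficiency_pct, 87.5)
  expect_equal(wk3$avg_tst_min, 420)
})

test_that("sleep efficiency is invariant to a common clock shift", {
  set.seed(101)
  for (rep in 1:25) {
    e <- random_entry()
    shift <- sample(0:1439, 1)
    shifted <- diary_entry(
      e$participant_id, e$date,
      (e$bedtime + shift) %% 1440, (e$try_to_sleep_time + shift) %% 1440,
      e$sol_min, e$awakenings, e$waso_min,
      (e$final_wake_time + shift) %% 1440,
      (e$out_of_bed_time + shift) %% 1440)
    expect_equal(derive_entry_metrics(shifted), derive_entry_metrics(e))
  }
})

test_that("weekly aggregation is permutation invariant and matches identical nights", {
  set.seed(202)
  entries <- lapply(1:6, function(i) random_entry(date = as.Date("2022-01-10") + i))
  perm <- sample(length(entries))
  expect_equal(aggregate_week(entries[perm]), aggregate_week(entries))
  # weekly SE equals nightly SE when all nights are identical
  one <- derive_entry_metrics(make_identical_week(1)[[1]])
  expect_equal(aggregate_week(make_identical_week())$sleep_efficiency_pct,
               one$sleep_efficiency_pct)
})

test_that("diary CSV reader validates rows with line numbers", {
  ok <- data.frame(
    participant_id = c("P01", "P01"), date = c("2022-01-10", "2022-01-11"),
    bedtime = c("23:00", "23:30"), try_to_sleep_time = c("23:10", "23:30"),
    sol_min = c(20, 5), awakenings = c(1, 0), waso_min = c(15, 0),
    final_wake_time = c("06:30", "06:30"),
    out_of_bed_time = c("06:45", "06:40"))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(ok, f, row.names = FALSE)
  entries <- read_diary_csv(f)
  expect_length(entries, 2)
  expect_s3_class(entries[[1]], "diary_entry")

  bad <- ok
  bad$waso_min[2] <- 900  # exceeds time in bed on file line 3
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_diary_csv(f), "line 3", class = "dcbti_invalid_entry")

  write.csv(ok[-2], f, row.names = FALSE)
  expect_error(read_diary_csv(f), "missing column",
               class = "dcbti_schema_error")
})
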