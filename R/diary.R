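#' Construct and validate one night's sleep-diary entry
#'
#' One row of a Consensus-Sleep-Diary style morning report: when the sleeper
#' got into bed, started trying to sleep, how long falling asleep took, how
#' much and how often they were awake during the night, when they finally woke
#' and when they got out of bed. Clock fields may be "HH:MM" strings or
#' minutes since midnight; the night may wrap past midnight.
#'
#' Validation enforces nonnegative durations, a bed interval of positive
#' length and at most 18 h (longer intervals are treated as data-entry
#' errors), and total wakefulness not exceeding time in bed.
#'
#' @param participant_id Identifier string.
#' @param date Calendar date of the morning report (`Date` or "YYYY-MM-DD").
#' @param bedtime,try_to_sleep_time,final_wake_time,out_of_bed_time Clock
#'   times ("HH:MM" or minutes since midnight).
#' @param sol_min Sleep-onset latency, minutes.
#' @param awakenings Number of nighttime awakenings.
#' @param waso_min Wake after sleep onset, minutes.
#' @return A `diary_entry` object (list).
#' @examples
#' e <- diary_entry("P01", "2022-01-10", "23:00", "23:00", 30, 2, 30,
#'                  "07:00", "07:00")
#' derive_entry_metrics(e)
#' @export
diary_entry <- function(participant_id, date, bedtime, try_to_sleep_time,
                        sol_min, awakenings, waso_min,
                        final_wake_time, out_of_bed_time) {
  if (!is_count(sol_min)) {
    dcbti_error("sol_min must be a nonnegative integer minute count",
                "dcbti_invalid_entry")
  }
  if (!is_count(awakenings)) {
    dcbti_error("awakenings must be a nonnegative count",
                "dcbti_invalid_entry")
  }
  if (!is_count(waso_min)) {
    dcbti_error("waso_min must be a nonnegative integer minute count",
                "dcbti_invalid_entry")
  }
  e <- structure(
    list(
      participant_id    = as.character(participant_id),
      date              = as.Date(date),
      bedtime           = parse_clock(bedtime),
      try_to_sleep_time = parse_clock(try_to_sleep_time),
      sol_min           = as.integer(sol_min),
      awakenings        = as.integer(awakenings),
      waso_min          = as.integer(waso_min),
      final_wake_time   = parse_clock(final_wake_time),
      out_of_bed_time   = parse_clock(out_of_bed_time)
    ),
    class = "diary_entry"
  )
  derive_entry_metrics(e)  # errors on inconsistent durations
  e
}

#' @export
print.diary_entry <- function(x, ...) {
  m <- derive_entry_metrics(x)
  cat(sprintf(
    "<diary_entry> %s %s  bed %s  rise %s  TIB %d  TST %d  SE %.1f%%\n",
    x$participant_id, format(x$date), format_clock(x$bedtime),
    format_clock(x$out_of_bed_time), m$tib_min, m$tst_min,
    m$sleep_efficiency_pct))
  invisible(x)
}

#' Per-night sleep metrics from a diary entry
#'
#' Time in bed (TIB) runs from bedtime to out-of-bed, computed modulo 24 h.
#' Total sleep time (TST) removes all reported wakefulness: the pre-sleep
#' interval (bedtime to trying-to-sleep plus sleep-onset latency), wake after
#' sleep onset, and terminal wakefulness (final wake to out of bed). Sleep
#' efficiency is `100 * TST / TIB`, reported to 0.1 percentage point.
#'
#' @param entry A [diary_entry()].
#' @return An `entry_metrics` list: `tib_min`, `tst_min`,
#'   `sleep_efficiency_pct`.
#' @export
derive_entry_metrics <- function(entry) {
  tib <- clock_span(entry$bedtime, entry$out_of_bed_time)
  if (tib == 0L) {
    dcbti_error("out_of_bed_time equals bedtime: time in bed is zero",
                "dcbti_invalid_entry")
  }
  if (tib > 1080L) {
    dcbti_error(sprintf(
      "bedtime %s to out_of_bed_time %s spans %d min (> 18 h): rejected as a data error",
      format_clock(entry$bedtime), format_clock(entry$out_of_bed_time), tib),
      "dcbti_invalid_entry")
  }
  pre_sleep <- clock_span(entry$bedtime, entry$try_to_sleep_time) +
    entry$sol_min
  terminal <- clock_span(entry$final_wake_time, entry$out_of_bed_time)
  tst <- tib - pre_sleep - entry$waso_min - terminal
  if (tst < 0L) {
    dcbti_error(sprintf(
      paste0("reported wakefulness (pre-sleep %d + waso_min %d + terminal %d)",
             " exceeds time in bed (%d min)"),
      pre_sleep, entry$waso_min, terminal, tib),
      "dcbti_invalid_entry")
  }
  structure(
    list(tib_min = tib, tst_min = tst,
         sleep_efficiency_pct = round_half_up(100 * tst / tib, 1)),
    class = "entry_metrics"
  )
}

#' Aggregate one participant-week of diary entries
#'
#' Weekly sleep efficiency pools minutes (`100 * sum(TST) / sum(TIB)`) rather
#' than averaging nightly efficiencies. Bedtime averages and consistency
#' (sample SD, minutes) are computed on an axis unwrapped at 18:00; wake-time
#' statistics on an axis unwrapped at midnight. Weeks with fewer than
#' `min_days` logged nights are flagged `insufficient` and should not drive a
#' plan update.
#'
#' @param entries List of [diary_entry()] objects for one participant-week
#'   (may be empty).
#' @param min_days Minimum nights required for the metrics to be usable.
#' @param week_index Protocol week (1-7), carried through for bookkeeping.
#' @return A `weekly_metrics` object.
#' @examples
#' e <- diary_entry("P01", "2022-01-10", "23:00", "23:00", 30, 2, 30,
#'                  "07:00", "07:00")
#' aggregate_week(list(e, e, e))
#' @export
aggregate_week <- function(entries, min_days = 3, week_index = NA_integer_) {
  n <- length(entries)
  empty <- structure(
    list(week_index = as.integer(week_index), days_logged = n,
         insufficient = TRUE,
         avg_tst_min = NA_real_, avg_tib_min = NA_real_,
         sleep_efficiency_pct = NA_real_,
         avg_bedtime = NA_integer_, bedtime_consistency_min = NA_real_,
         avg_wake_time = NA_integer_, wake_consistency_min = NA_real_,
         avg_awakenings = NA_real_, avg_waso_min = NA_real_),
    class = "weekly_metrics"
  )
  if (n == 0) return(empty)
  per <- lapply(entries, derive_entry_metrics)
  tib <- vapply(per, `[[`, numeric(1), "tib_min")
  tst <- vapply(per, `[[`, numeric(1), "tst_min")
  bed <- vapply(entries, `[[`, integer(1), "bedtime")
  wake <- vapply(entries, `[[`, integer(1), "final_wake_time")
  out <- structure(
    list(
      week_index = as.integer(week_index),
      days_logged = n,
      insufficient = n < min_days,
      avg_tst_min = mean(tst),
      avg_tib_min = mean(tib),
      sleep_efficiency_pct = round_half_up(100 * sum(tst) / sum(tib), 1),
      avg_bedtime = clock_mean(bed, 1080L),
      bedtime_consistency_min = clock_sd(bed, 1080L),
      avg_wake_time = clock_mean(wake, 0L),
      wake_consistency_min = clock_sd(wake, 0L),
      avg_awakenings = mean(vapply(entries, `[[`, integer(1), "awakenings")),
      avg_waso_min = mean(vapply(entries, `[[`, integer(1), "waso_min"))
    ),
    class = "weekly_metrics"
  )
  out
}

#' @export
print.weekly_metrics <- function(x, ...) {
  cat(sprintf("<weekly_metrics> week %s, %d night(s) logged%s\n",
              ifelse(is.na(x$week_index), "?", x$week_index), x$days_logged,
              if (x$insufficient) " [insufficient]" else ""))
  if (!x$insufficient) {
    cat(sprintf("  SE %.1f%%  TST %.0f min  TIB %.0f min\n",
                x$sleep_efficiency_pct, x$avg_tst_min, x$avg_tib_min))
    cat(sprintf("  bedtime %s (SD %.0f min)  wake %s (SD %.0f min)\n",
                format_clock(x$avg_bedtime),
                x$bedtime_consistency_min %||% NA,
                format_clock(x$avg_wake_time), x$wake_consistency_min))
    cat(sprintf("  awakenings %.1f/night  WASO %.0f min/night\n",
                x$avg_awakenings, x$avg_waso_min))
  }
  invisible(x)
}

#' Read a diary CSV
#'
#' Expects one row per night with columns `participant_id, date, bedtime,
#' try_to_sleep_time, sol_min, awakenings, waso_min, final_wake_time,
#' out_of_bed_time`; clock fields "HH:MM" 24-hour, dates ISO 8601. Every row
#' is validated; all offending rows are reported together with their file
#' line numbers.
#'
#' @param path Path to a CSV file.
#' @return List of [diary_entry()] objects.
#' @export
read_diary_csv <- function(path) {
  cols <- c("participant_id", "date", "bedtime", "try_to_sleep_time",
            "sol_min", "awakenings", "waso_min", "final_wake_time",
            "out_of_bed_time")
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    dcbti_error(sprintf("diary CSV missing column(s): %s",
                        paste(missing, collapse = ", ")),
                "dcbti_schema_error")
  }
  entries <- vector("list", nrow(df))
  problems <- character(0)
  for (i in seq_len(nrow(df))) {
    entries[[i]] <- tryCatch(
      diary_entry(df$participant_id[i], df$date[i], df$bedtime[i],
                  df$try_to_sleep_time[i],
                  suppressWarnings(as.numeric(df$sol_min[i])),
                  suppressWarnings(as.numeric(df$awakenings[i])),
                  suppressWarnings(as.numeric(df$waso_min[i])),
                  df$final_wake_time[i], df$out_of_bed_time[i]),
      dcbti_error = function(e) {
        problems <<- c(problems,
                       sprintf("line %d: %s", i + 1L, conditionMessage(e)))
        NULL
      })
  }
  if (length(problems)) {
    dcbti_error(paste0("invalid diary rows:\n  ",
                       paste(problems, collapse = "\n  ")),
                "dcbti_invalid_entry")
  }
  entries
}
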