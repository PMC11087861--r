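#' Weekly and overall adherence rates
#'
#' A participant is adherent in a week when they engaged with the app at
#' least `min_days` days that week (default 4 of 7). Weekly rates are the
#' percentage of enrolled participants adherent that week, rounded half-up
#' to whole percent; the overall rate is the mean of the seven *unrounded*
#' weekly rates, then rounded. The study-level verdict is acceptable when
#' the overall rate is at least `criterion_pct` (default 75%).
#'
#' @param days_by_week Integer matrix, participants x weeks, of engaged-day
#'   counts (see [engagement_days_matrix()]); or a data frame with columns
#'   `participant_id`, `week`, `days_active`.
#' @param n_enrolled Number of enrolled participants (the denominator; rows
#'   absent from `days_by_week` count as zero days).
#' @param min_days Engaged days per week required for adherence.
#' @param criterion_pct Acceptability criterion on the overall rate.
#' @return An `adherence_report` list: `weekly_pct` (length-7 integer),
#'   `overall_pct`, `acceptable`, plus the unrounded rates.
#' @examples
#' m <- matrix(7, nrow = 30, ncol = 7)
#' m[1, 1] <- 2
#' weekly_adherence(m, n_enrolled = 30)
#' @export
weekly_adherence <- function(days_by_week, n_enrolled, min_days = 4,
                             criterion_pct = 75) {
  if (!is_count(n_enrolled) || n_enrolled == 0) {
    dcbti_error("n_enrolled must be a positive count", "dcbti_config_error")
  }
  if (is.data.frame(days_by_week)) {
    need <- c("participant_id", "week", "days_active")
    if (!all(need %in% names(days_by_week))) {
      dcbti_error("data frame needs participant_id, week, days_active",
                  "dcbti_schema_error")
    }
    ids <- unique(days_by_week$participant_id)
    m <- matrix(0L, nrow = length(ids), ncol = 7,
                dimnames = list(ids, NULL))
    m[cbind(match(days_by_week$participant_id, ids),
            days_by_week$week)] <- days_by_week$days_active
    days_by_week <- m
  }
  if (ncol(days_by_week) != 7) {
    dcbti_error("days_by_week must cover weeks 1-7", "dcbti_schema_error")
  }
  adherent <- colSums(days_by_week >= min_days)
  raw <- 100 * adherent / n_enrolled
  overall_raw <- mean(raw)
  structure(
    list(weekly_pct = as.integer(round_half_up(raw)),
         weekly_pct_raw = raw,
         overall_pct = as.integer(round_half_up(overall_raw)),
         overall_pct_raw = overall_raw,
         adherent_counts = as.integer(adherent),
         n_enrolled = as.integer(n_enrolled),
         acceptable = round_half_up(overall_raw) >= criterion_pct),
    class = "adherence_report"
  )
}

#' @export
print.adherence_report <- function(x, ...) {
  cat(sprintf("<adherence_report> weekly %s%%; overall %d%% (%s)\n",
              paste(x$weekly_pct, collapse = "/"), x$overall_pct,
              if (x$acceptable) "acceptable" else "below criterion"))
  invisible(x)
}

#' Engaged-day counts per participant-week from an engagement log
#'
#' Maps each interaction date to a protocol week (1-7) relative to each
#' participant's enrollment date and counts distinct engaged days per week.
#' Dates outside the 7 protocol weeks are rejected.
#'
#' @param engagement Data frame with columns `participant_id`, `date`.
#' @param enrollment Named vector/list of enrollment `Date`s by participant
#'   id, or a single date shared by all.
#' @param ids Participant ids fixing the row order (defaults to those seen).
#' @return Integer matrix, participants x 7 weeks.
#' @export
engagement_days_matrix <- function(engagement, enrollment,
                                   ids = unique(engagement$participant_id)) {
  dates <- as.Date(engagement$date)
  enr <- if (length(enrollment) == 1 && is.null(names(enrollment))) {
    stats::setNames(rep(as.Date(enrollment), length(ids)), ids)
  } else {
    stats::setNames(as.Date(unlist(enrollment)), names(enrollment))
  }
  day_idx <- as.integer(dates - enr[engagement$participant_id])
  if (anyNA(day_idx) || any(day_idx < 0 | day_idx >= 49)) {
    dcbti_error("engagement dates must fall within the 7 protocol weeks",
                "dcbti_invalid_entry")
  }
  week <- day_idx %/% 7L + 1L
  key <- paste(engagement$participant_id, dates)
  keep <- !duplicated(key)
  m <- matrix(0L, nrow = length(ids), ncol = 7, dimnames = list(ids, NULL))
  tab <- table(factor(engagement$participant_id[keep], levels = ids),
               factor(week[keep], levels = 1:7))
  m[] <- as.integer(tab)
  m
}

#' Attrition rate
#'
#' Anyone who did not complete data collection through week 7 counts toward
#' attrition. The study criterion is an attrition rate of at most
#' `criterion_pct` (default 25%).
#'
#' @param completed Logical vector, one flag per enrolled participant.
#' @param criterion_pct Feasibility bound on the attrition percentage.
#' @return An `attrition_report` list: `n_enrolled`, `n_withdrawn`,
#'   `attrition_pct` (one decimal), `feasible`.
#' @examples
#' attrition_rate(rep(TRUE, 30))
#' @export
attrition_rate <- function(completed, criterion_pct = 25) {
  if (!is.logical(completed) || anyNA(completed)) {
    dcbti_error("completed must be a logical vector without NAs",
                "dcbti_invalid_response")
  }
  n <- length(completed)
  w <- sum(!completed)
  pct <- round_half_up(100 * w / n, 1)
  structure(
    list(n_enrolled = n, n_withdrawn = w, attrition_pct = pct,
         feasible = pct <= criterion_pct),
    class = "attrition_report"
  )
}

#' @export
print.attrition_report <- function(x, ...) {
  cat(sprintf("<attrition_report> %d/%d withdrawn (%.1f%%): %s\n",
              x$n_withdrawn, x$n_enrolled, x$attrition_pct,
              if (x$feasible) "feasible" else "not feasible"))
  invisible(x)
}

#' Acceptability: usefulness, satisfaction, recommendation
#'
#' Usefulness is rated 1 (not at all) to 4 (very) per app feature;
#' satisfaction and willingness to recommend 1 (strongly disagree) to
#' 5 (strongly agree). The pre-set criteria: at least 75% of participants
#' find at least one feature at least a little useful (rating >=
#' `usefulness_cutoff`, default 2); at least 80% are satisfied (>= 4) and at
#' least 80% would recommend (>= 4).
#'
#' @param usefulness Numeric matrix, participants x features, ratings 1-4.
#' @param satisfaction,recommend Numeric vectors of ratings 1-5.
#' @param usefulness_cutoff Rating counted as "at least a little useful"
#'   (2 by default; set 3 for "moderately useful or more").
#' @return An `acceptability_report` list with per-feature percentages, the
#'   any-feature percentage, satisfaction/recommend percentages, and the
#'   three verdicts.
#' @export
acceptability_summary <- function(usefulness, satisfaction, recommend,
                                  usefulness_cutoff = 2) {
  usefulness <- as.matrix(usefulness)
  if (anyNA(usefulness) || any(usefulness < 1 | usefulness > 4)) {
    dcbti_error("usefulness ratings must be complete and in 1-4",
                "dcbti_invalid_response")
  }
  for (v in list(satisfaction, recommend)) {
    if (anyNA(v) || any(v < 1 | v > 5)) {
      dcbti_error("satisfaction/recommend ratings must be complete and in 1-5",
                  "dcbti_invalid_response")
    }
  }
  n <- nrow(usefulness)
  feature_pct <- pct_of(colSums(usefulness >= usefulness_cutoff), n)
  any_pct <- pct_of(sum(rowSums(usefulness >= usefulness_cutoff) > 0), n)
  sat_pct <- pct_of(sum(satisfaction >= 4), length(satisfaction))
  rec_pct <- pct_of(sum(recommend >= 4), length(recommend))
  structure(
    list(n = n,
         feature_useful_pct = feature_pct,
         any_feature_useful_pct = any_pct,
         satisfaction_pct = sat_pct,
         recommend_pct = rec_pct,
         usefulness_cutoff = usefulness_cutoff,
         usefulness_acceptable = any_pct >= 75,
         satisfaction_acceptable = sat_pct >= 80,
         recommend_acceptable = rec_pct >= 80),
    class = "acceptability_report"
  )
}

#' @export
print.acceptability_report <- function(x, ...) {
  cat(sprintf(
    paste0("<acceptability_report> n=%d: any feature useful %d%%, ",
           "satisfied %d%%, would recommend %d%%\n"),
    x$n, x$any_feature_useful_pct, x$satisfaction_pct, x$recommend_pct))
  invisible(x)
}

#' Change scores and Cohen's d
#'
#' For a decrease-coded outcome the mean change is baseline minus follow-up.
#' Two standardizations of Cohen's d are computed: `d_pooled`, the mean
#' change over the pooled SD of the two timepoints, and `d_change`, the mean
#' change over the SD of the paired change scores (available only when raw
#' paired vectors are supplied; otherwise flagged unavailable). Inputs may
#' be raw vectors or summary lists `list(mean=, sd=, n=)`.
#'
#' @param baseline,followup Numeric vectors, or summary lists with elements
#'   `mean`, `sd`, `n`.
#' @param paired When `TRUE` (default) and raw vectors are given, they must
#'   be equal length and aligned by participant.
#' @return A `change_stats` list: means, SDs, `mean_change`, `d_pooled`,
#'   `d_change` (NA when unavailable), `n`.
#' @examples
#' change_statistics(list(mean = 18.5, sd = 4.6, n = 30),
#'                   list(mean = 10.4, sd = 4.2, n = 30))
#' @export
change_statistics <- function(baseline, followup, paired = TRUE) {
  as_summary <- function(x) {
    if (is.list(x)) {
      list(mean = x$mean, sd = x$sd, n = x$n, raw = NULL)
    } else {
      list(mean = mean(x), sd = stats::sd(x), n = length(x), raw = x)
    }
  }
  b <- as_summary(baseline)
  f <- as_summary(followup)
  if (paired && !is.null(b$raw) && !is.null(f$raw) &&
      length(b$raw) != length(f$raw)) {
    dcbti_error("paired change statistics require equal-length vectors",
                "dcbti_invalid_response")
  }
  mean_change <- b$mean - f$mean
  # equal-n pooled SD reduces to sqrt((s1^2 + s2^2) / 2)
  pooled_sd <- sqrt(((b$n - 1) * b$sd^2 + (f$n - 1) * f$sd^2) /
                      (b$n + f$n - 2))
  d_pooled <- if (pooled_sd > 0) mean_change / pooled_sd else
    ifelse(mean_change == 0, 0, NA_real_)
  d_change <- NA_real_
  change_sd <- NA_real_
  if (paired && !is.null(b$raw) && !is.null(f$raw)) {
    diffs <- b$raw - f$raw
    change_sd <- stats::sd(diffs)
    d_change <- if (isTRUE(change_sd > 0)) mean(diffs) / change_sd else
      ifelse(all(diffs == diffs[1]) && mean(diffs) == 0, 0, NA_real_)
  }
  structure(
    list(mean_baseline = b$mean, sd_baseline = b$sd,
         mean_followup = f$mean, sd_followup = f$sd,
         n_baseline = b$n, n_followup = f$n,
         mean_change = mean_change, pooled_sd = pooled_sd,
         change_sd = change_sd,
         d_pooled = d_pooled, d_change = d_change,
         d_change_available = !is.na(d_change)),
    class = "change_stats"
  )
}

#' @export
print.change_stats <- function(x, ...) {
  cat(sprintf(
    paste0("<change_stats> %.1f (SD %.1f) -> %.1f (SD %.1f), ",
           "change %.1f\n  Cohen's d: pooled %.2f, change-score %s\n"),
    x$mean_baseline, x$sd_baseline, x$mean_followup, x$sd_followup,
    x$mean_change, x$d_pooled,
    if (x$d_change_available) sprintf("%.2f", x$d_change) else "unavailable"))
  invisible(x)
}

#' Sleep-medication use at two timepoints
#'
#' Compares the proportion of participants using a medication class at
#' baseline and follow-up. The default Pearson chi-square test (no
#' continuity correction) follows the study's analysis plan and treats the
#' two timepoints as a 2x2 of user counts; McNemar's test is offered for the
#' paired design but requires the discordant counts (started/stopped) and
#' returns an explicit unavailable result without them.
#'
#' @param n Number of participants.
#' @param baseline_users,followup_users User counts at each timepoint.
#' @param discordant Optional `c(stopped, started)` discordant-pair counts
#'   (used at baseline only / used at follow-up only) for McNemar.
#' @param method `"chi2"` (default) or `"mcnemar"`.
#' @return A `medication_comparison` list: whole-percent proportions, the
#'   test statistic and p-value (NA with `available = FALSE` when McNemar is
#'   requested without discordant counts), and the method used.
#' @examples
#' medication_use_comparison(30, 7, 1)
#' @export
medication_use_comparison <- function(n, baseline_users, followup_users,
                                      discordant = NULL,
                                      method = c("chi2", "mcnemar")) {
  method <- match.arg(method)
  if (baseline_users > n || followup_users > n) {
    dcbti_error("user counts cannot exceed n", "dcbti_invalid_response")
  }
  out <- list(
    n = n,
    baseline_users = baseline_users, followup_users = followup_users,
    baseline_pct = pct_of(baseline_users, n),
    followup_pct = pct_of(followup_users, n),
    method = method, statistic = NA_real_, p_value = NA_real_,
    available = TRUE
  )
  if (method == "chi2") {
    tab <- rbind(baseline = c(user = baseline_users, nonuser = n - baseline_users),
                 followup = c(user = followup_users, nonuser = n - followup_users))
    if (baseline_users == followup_users) {
      out$statistic <- 0
      out$p_value <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      out$statistic <- unname(ct$statistic)
      out$p_value <- ct$p.value
    }
  } else {
    if (is.null(discordant) || length(discordant) != 2) {
      out$available <- FALSE
    } else {
      stopped <- discordant[1]
      started <- discordant[2]
      both <- baseline_users - stopped
      neither <- n - baseline_users - started
      if (both < 0 || neither < 0 ||
          followup_users != both + started) {
        dcbti_error("discordant counts inconsistent with user totals",
                    "dcbti_invalid_response")
      }
      tab <- matrix(c(both, stopped, started, neither), nrow = 2,
                    dimnames = list(baseline = c("user", "nonuser"),
                                    followup = c("user", "nonuser")))
      if (stopped + started == 0) {
        out$statistic <- 0
        out$p_value <- 1
      } else {
        mt <- stats::mcnemar.test(tab)
        out$statistic <- unname(mt$statistic)
        out$p_value <- mt$p.value
      }
    }
  }
  structure(out, class = "medication_comparison")
}

#' @export
print.medication_comparison <- function(x, ...) {
  cat(sprintf("<medication_comparison> %d (%d%%) -> %d (%d%%) of %d",
              x$baseline_users, x$baseline_pct, x$followup_users,
              x$followup_pct, x$n))
  if (x$available) {
    cat(sprintf("; %s statistic %.3f, p %.4g\n", x$method, x$statistic,
                x$p_value))
  } else {
    cat(sprintf("; %s unavailable (no discordant counts)\n", x$method))
  }
  invisible(x)
}

#' ISI clinical-band table at two timepoints
#'
#' Counts and whole-percent shares of participants in each clinical band
#' (none 0-7, mild 8-14, moderate 15-21, severe 22-28) at baseline and
#' follow-up.
#'
#' @param baseline,week7 Integer vectors of ISI totals.
#' @return An `isi_band_table` data frame: `band`, `baseline_n`,
#'   `baseline_pct`, `week7_n`, `week7_pct`.
#' @export
isi_band_table <- function(baseline, week7) {
  bl <- table(isi_band(baseline))
  w7 <- table(isi_band(week7))
  out <- data.frame(
    band = names(bl),
    baseline_n = as.integer(bl),
    baseline_pct = as.integer(pct_of(as.integer(bl), length(baseline))),
    week7_n = as.integer(w7),
    week7_pct = as.integer(pct_of(as.integer(w7), length(week7))),
    stringsAsFactors = FALSE
  )
  class(out) <- c("isi_band_table", "data.frame")
  out
}

#' Pearson correlation between two instrument score vectors
#'
#' @param x,y Equal-length paired numeric vectors, `n >= 3`.
#' @return Pearson product-moment correlation coefficient.
#' @export
score_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    dcbti_error("score_correlation needs equal-length paired vectors, n >= 3",
                "dcbti_invalid_response")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    dcbti_error("correlation undefined: a score vector has zero variance",
                "dcbti_degenerate")
  }
  stats::cor(x, y)
}
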