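#' Full feasibility and outcome evaluation of a cohort dataset
#'
#' Recomputes every feasibility and efficacy statistic from the raw tables:
#' weekly/overall adherence from the engagement log, attrition from the
#' completion flags, acceptability proportions and verdicts, ISI and
#' DBAS-16 change statistics with both Cohen's d variants, the ISI
#' clinical-band table, prescription and OTC medication-use comparisons,
#' the baseline ISI-DBAS correlation, and the weekly pooled
#' sleep-efficiency trajectory from the diaries.
#'
#' @param ds A [cohort_dataset()] with baseline and week-7 assessments.
#' @param min_days Engaged days per week required for adherence (default 4).
#' @param usefulness_cutoff Rating counted as at least a little useful.
#' @param med_method `"chi2"` (default) or `"mcnemar"` for the medication
#'   comparisons; discordant counts are derived from the paired flags.
#' @return A `feasibility_report` list of the component reports.
#' @examples
#' ds <- run_trial(sim_params(n_participants = 6, seed = 11))
#' evaluate_cohort(ds)
#' @export
evaluate_cohort <- function(ds, min_days = 4, usefulness_cutoff = 2,
                            med_method = c("chi2", "mcnemar")) {
  med_method <- match.arg(med_method)
  ids <- ds$participants$participant_id
  n <- length(ids)

  days <- engagement_days_matrix(
    ds$engagement,
    stats::setNames(as.Date(ds$participants$enrollment_date), ids),
    ids = ids)
  adherence <- weekly_adherence(days, n_enrolled = n, min_days = min_days)
  attrition <- attrition_rate(ds$participants$completed)

  accept <- NULL
  if (nrow(ds$acceptability)) {
    accept <- acceptability_summary(
      as.matrix(ds$acceptability[paste0("feature", 1:10)]),
      ds$acceptability$satisfaction, ds$acceptability$recommend,
      usefulness_cutoff = usefulness_cutoff)
  }

  score_rows <- function(tbl, n_items, scorer) {
    items <- as.matrix(tbl[paste0("item", seq_len(n_items))])
    vapply(seq_len(nrow(tbl)), function(i) scorer(items[i, ]), numeric(1))
  }
  isi_bl <- ds$isi[ds$isi$timepoint == "baseline", ]
  isi_w7 <- ds$isi[ds$isi$timepoint == "week7", ]
  isi_bl_tot <- score_rows(isi_bl, 7, function(x) score_isi(x)$total)
  isi_w7_tot <- score_rows(isi_w7, 7, function(x) score_isi(x)$total)
  paired_ids <- intersect(isi_bl$participant_id, isi_w7$participant_id)
  isi_change <- change_statistics(
    isi_bl_tot[match(paired_ids, isi_bl$participant_id)],
    isi_w7_tot[match(paired_ids, isi_w7$participant_id)])
  bands <- isi_band_table(isi_bl_tot, isi_w7_tot)

  dbas_bl <- ds$dbas[ds$dbas$timepoint == "baseline", ]
  dbas_w7 <- ds$dbas[ds$dbas$timepoint == "week7", ]
  dbas_bl_tot <- score_rows(dbas_bl, 16, function(x) score_dbas(x)$total)
  dbas_w7_tot <- score_rows(dbas_w7, 16, function(x) score_dbas(x)$total)
  dpaired <- intersect(dbas_bl$participant_id, dbas_w7$participant_id)
  dbas_change <- change_statistics(
    dbas_bl_tot[match(dpaired, dbas_bl$participant_id)],
    dbas_w7_tot[match(dpaired, dbas_w7$participant_id)])

  both <- intersect(isi_bl$participant_id, dbas_bl$participant_id)
  baseline_cor <- score_correlation(
    isi_bl_tot[match(both, isi_bl$participant_id)],
    dbas_bl_tot[match(both, dbas_bl$participant_id)])

  med_cmp <- function(col) {
    bl <- ds$medications[ds$medications$timepoint == "baseline", ]
    w7 <- ds$medications[ds$medications$timepoint == "week7", ]
    common <- intersect(bl$participant_id, w7$participant_id)
    b <- bl[[col]][match(common, bl$participant_id)]
    f <- w7[[col]][match(common, w7$participant_id)]
    medication_use_comparison(
      length(common), sum(b), sum(f),
      discordant = c(sum(b & !f), sum(!b & f)), method = med_method)
  }

  structure(
    list(n_enrolled = n,
         adherence = adherence, attrition = attrition,
         acceptability = accept,
         isi_change = isi_change, isi_bands = bands,
         dbas_change = dbas_change,
         baseline_isi_dbas_cor = baseline_cor,
         medication_rx = med_cmp("prescription"),
         medication_otc = med_cmp("otc"),
         weekly_se = weekly_se_trajectory(ds)),
    class = "feasibility_report"
  )
}

#' Weekly pooled sleep-efficiency trajectory
#'
#' Pools each participant's logged nights by protocol week (dates relative
#' to enrollment) and returns the per-week mean of the participant-level
#' pooled sleep efficiencies.
#'
#' @param ds A [cohort_dataset()].
#' @return Numeric vector, one mean SE percentage per week (NA for weeks
#'   with no diaries).
#' @export
weekly_se_trajectory <- function(ds) {
  if (!nrow(ds$diaries)) return(rep(NA_real_, 7))
  enroll <- stats::setNames(as.Date(ds$participants$enrollment_date),
                            ds$participants$participant_id)
  d <- ds$diaries
  week <- as.integer(as.Date(d$date) - enroll[d$participant_id]) %/% 7L + 1L
  se <- matrix(NA_real_, nrow(ds$participants), 7,
               dimnames = list(ds$participants$participant_id, NULL))
  for (w in sort(unique(week))) {
    sub <- d[week == w, ]
    for (id in unique(sub$participant_id)) {
      entries <- diary_entries_from_table(sub[sub$participant_id == id, ])
      m <- aggregate_week(entries, min_days = 1, week_index = w)
      se[id, w] <- m$sleep_efficiency_pct
    }
  }
  colMeans(se, na.rm = TRUE)
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat("Feasibility and outcome report\n")
  cat("==============================\n")
  cat(sprintf("Enrolled: %d\n\n", x$n_enrolled))
  cat(sprintf("Adherence (>= 4 days/week): weekly %s%%\n",
              paste(x$adherence$weekly_pct, collapse = "/")))
  cat(sprintf("  overall %d%% -- %s (criterion >= 75%%)\n",
              x$adherence$overall_pct,
              if (x$adherence$acceptable) "acceptable" else "below criterion"))
  cat(sprintf("Attrition: %d/%d (%.1f%%) -- %s (criterion <= 25%%)\n",
              x$attrition$n_withdrawn, x$attrition$n_enrolled,
              x$attrition$attrition_pct,
              if (x$attrition$feasible) "feasible" else "not feasible"))
  if (!is.null(x$acceptability)) {
    a <- x$acceptability
    cat(sprintf(
      "Acceptability: any feature useful %d%%, satisfied %d%%, recommend %d%%\n",
      a$any_feature_useful_pct, a$satisfaction_pct, a$recommend_pct))
  }
  cat("\nInsomnia Severity Index\n")
  cat(sprintf("  %.1f (SD %.1f) -> %.1f (SD %.1f); change %.1f; d(pooled) %.2f, d(change) %.2f\n",
              x$isi_change$mean_baseline, x$isi_change$sd_baseline,
              x$isi_change$mean_followup, x$isi_change$sd_followup,
              x$isi_change$mean_change, x$isi_change$d_pooled,
              x$isi_change$d_change))
  cat("  Clinical range           baseline n (%)   week 7 n (%)\n")
  labels <- c(none = "No clinical insomnia (0-7) ",
              mild = "Mild disturbance (8-14)    ",
              moderate = "Moderate insomnia (15-21)  ",
              severe = "Severe insomnia (22-28)    ")
  for (i in seq_len(nrow(x$isi_bands))) {
    b <- x$isi_bands[i, ]
    cat(sprintf("  %s %3d (%3d)       %3d (%3d)\n", labels[b$band],
                b$baseline_n, b$baseline_pct, b$week7_n, b$week7_pct))
  }
  cat("\nDBAS-16\n")
  cat(sprintf("  %.1f (SD %.1f) -> %.1f (SD %.1f); change %.1f; d(pooled) %.2f\n",
              x$dbas_change$mean_baseline, x$dbas_change$sd_baseline,
              x$dbas_change$mean_followup, x$dbas_change$sd_followup,
              x$dbas_change$mean_change, x$dbas_change$d_pooled))
  cat(sprintf("  baseline ISI-DBAS correlation R = %.3f\n",
              x$baseline_isi_dbas_cor))
  cat("\nSleep medication use\n")
  for (nm in c("medication_rx", "medication_otc")) {
    m <- x[[nm]]
    cat(sprintf("  %-13s %d (%d%%) -> %d (%d%%), %s p = %.4g\n",
                if (nm == "medication_rx") "prescription:" else "OTC:",
                m$baseline_users, m$baseline_pct, m$followup_users,
                m$followup_pct, m$method, m$p_value))
  }
  se <- x$weekly_se
  if (any(!is.na(se))) {
    cat(sprintf("\nWeekly mean sleep efficiency: %s\n",
                paste(sprintf("%.1f", se), collapse = " ")))
  }
  invisible(x)
}

#' Flatten a feasibility report to a named list of scalars
#'
#' Convenience for JSON export (CLI `evaluate` subcommand).
#'
#' @param report A [evaluate_cohort()] result.
#' @return Named list of scalar summaries.
#' @export
report_as_list <- function(report) {
  list(
    n_enrolled = report$n_enrolled,
    weekly_adherence_pct = report$adherence$weekly_pct,
    overall_adherence_pct = report$adherence$overall_pct,
    adherence_acceptable = report$adherence$acceptable,
    attrition_pct = report$attrition$attrition_pct,
    attrition_feasible = report$attrition$feasible,
    any_feature_useful_pct =
      report$acceptability$any_feature_useful_pct %||% NA,
    satisfaction_pct = report$acceptability$satisfaction_pct %||% NA,
    recommend_pct = report$acceptability$recommend_pct %||% NA,
    isi_mean_baseline = report$isi_change$mean_baseline,
    isi_mean_week7 = report$isi_change$mean_followup,
    isi_mean_change = report$isi_change$mean_change,
    isi_d_pooled = report$isi_change$d_pooled,
    isi_d_change = report$isi_change$d_change,
    dbas_mean_change = report$dbas_change$mean_change,
    baseline_isi_dbas_cor = report$baseline_isi_dbas_cor,
    rx_baseline_pct = report$medication_rx$baseline_pct,
    rx_week7_pct = report$medication_rx$followup_pct,
    otc_baseline_pct = report$medication_otc$baseline_pct,
    otc_week7_pct = report$medication_otc$followup_pct,
    weekly_mean_se_pct = report$weekly_se
  )
}
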