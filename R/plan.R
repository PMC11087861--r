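#' Sleep-restriction titration policy
#'
#' The rule set for the weekly adjustment of recommended time in bed (TIB).
#' TIB moves in `step_min` increments toward a sleep-efficiency target:
#' `se_threshold_pct` (default 85%), or `se_threshold_older_pct` (default
#' 80%) for sleepers aged `older_age_cutoff_years` and over. A hold band of
#' `hold_band_pct` percentage points below the applicable threshold prevents
#' oscillation: TIB is decreased only when sleep efficiency falls below
#' threshold minus band. Recommended TIB is clamped to
#' `[tib_floor_min, tib_ceiling_min]` (defaults 5-10 h; the 5 h floor is
#' standard sleep-restriction safety practice).
#'
#' @param se_threshold_pct,se_threshold_older_pct Sleep-efficiency targets
#'   (percent) for adults under / at-or-over the age cutoff.
#' @param older_age_cutoff_years Age (years) at which the lower target
#'   applies.
#' @param step_min Titration step, minutes.
#' @param tib_floor_min,tib_ceiling_min Bounds on recommended TIB, minutes;
#'   both must be multiples of `step_min`.
#' @param hold_band_pct Width (percentage points) of the hold band below the
#'   threshold.
#' @param late_morning,early_afternoon Default clock anchors ("HH:MM") for
#'   the daytime just-in-time notifications.
#' @return A `titration_policy` object.
#' @examples
#' titration_policy()
#' @export
titration_policy <- function(se_threshold_pct = 85,
                             se_threshold_older_pct = 80,
                             older_age_cutoff_years = 65,
                             step_min = 15,
                             tib_floor_min = 300,
                             tib_ceiling_min = 600,
                             hold_band_pct = 5,
                             late_morning = "10:30",
                             early_afternoon = "14:00") {
  if (!(se_threshold_pct > 0 && se_threshold_pct <= 100) ||
      !(se_threshold_older_pct > 0 && se_threshold_older_pct <= 100)) {
    dcbti_error("sleep-efficiency thresholds must lie in (0, 100]",
                "dcbti_config_error")
  }
  if (tib_floor_min >= tib_ceiling_min) {
    dcbti_error("tib_floor_min must be below tib_ceiling_min",
                "dcbti_config_error")
  }
  if (tib_floor_min %% step_min != 0 || tib_ceiling_min %% step_min != 0) {
    dcbti_error("TIB floor and ceiling must be multiples of step_min",
                "dcbti_config_error")
  }
  if (hold_band_pct < 0) {
    dcbti_error("hold_band_pct must be nonnegative", "dcbti_config_error")
  }
  structure(
    list(se_threshold_pct = se_threshold_pct,
         se_threshold_older_pct = se_threshold_older_pct,
         older_age_cutoff_years = older_age_cutoff_years,
         step_min = as.integer(step_min),
         tib_floor_min = as.integer(tib_floor_min),
         tib_ceiling_min = as.integer(tib_ceiling_min),
         hold_band_pct = hold_band_pct,
         late_morning = parse_clock(late_morning),
         early_afternoon = parse_clock(early_afternoon)),
    class = "titration_policy"
  )
}

#' @export
print.titration_policy <- function(x, ...) {
  cat(sprintf(
    paste0("<titration_policy> SE target %g%% (%g%% at age >= %g), ",
           "step %d min,\n  TIB range [%d, %d] min, hold band %g pts\n"),
    x$se_threshold_pct, x$se_threshold_older_pct, x$older_age_cutoff_years,
    x$step_min, x$tib_floor_min, x$tib_ceiling_min, x$hold_band_pct))
  invisible(x)
}

#' Read a titration policy from a JSON or YAML config file
#'
#' Keys mirror the arguments of [titration_policy()]; absent keys keep their
#' defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `titration_policy`.
#' @export
read_policy_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      dcbti_error("the 'yaml' package is required to read YAML configs",
                  "dcbti_config_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(titration_policy))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    dcbti_error(sprintf("unknown policy key(s): %s",
                        paste(extra, collapse = ", ")),
                "dcbti_config_error")
  }
  do.call(titration_policy, cfg)
}

applicable_threshold <- function(age_years, policy) {
  if (age_years >= policy$older_age_cutoff_years) {
    policy$se_threshold_older_pct
  } else {
    policy$se_threshold_pct
  }
}

#' Weekly time-in-bed titration
#'
#' Applies the sleep-restriction rule to last week's pooled sleep efficiency:
#' at or above the age-appropriate threshold with a low reported unmet sleep
#' need, recommended TIB increases by one step; below threshold minus the
#' hold band it decreases by one step; otherwise it holds. The result is
#' clamped to the policy bounds and always stays on the step grid. Weeks
#' flagged insufficient leave the prior recommendation unchanged.
#'
#' @param metrics A `weekly_metrics` object (or a bare sleep-efficiency
#'   percentage, taken as a sufficient week).
#' @param unmet_need `"low"` or `"high"` reported unmet sleep need; only a
#'   low unmet need permits the increase branch.
#' @param age_years Participant age, years.
#' @param prior_tib_min Last week's recommended TIB (minutes, on the step
#'   grid, within bounds).
#' @param policy A [titration_policy()].
#' @return Integer minutes of recommended TIB for the coming week, with
#'   attributes `branch` (`"increase"`, `"decrease"`, `"hold"`, or
#'   `"insufficient"`) and `threshold_applied_pct`.
#' @examples
#' titrate_time_in_bed(90, "low", 55, 420, titration_policy())   # 435
#' titrate_time_in_bed(70, "low", 55, 315, titration_policy())   # 300 (floor)
#' @export
titrate_time_in_bed <- function(metrics, unmet_need, age_years,
                                prior_tib_min, policy = titration_policy()) {
  if (!unmet_need %in% c("low", "high")) {
    dcbti_error("unmet_need must be 'low' or 'high'", "dcbti_config_error")
  }
  if (prior_tib_min %% policy$step_min != 0) {
    dcbti_error(sprintf("prior_tib_min %s is off the %d-min grid",
                        prior_tib_min, policy$step_min),
                "dcbti_config_error")
  }
  if (prior_tib_min < policy$tib_floor_min ||
      prior_tib_min > policy$tib_ceiling_min) {
    dcbti_error(sprintf("prior_tib_min %s outside [%d, %d]",
                        prior_tib_min, policy$tib_floor_min,
                        policy$tib_ceiling_min),
                "dcbti_config_error")
  }
  thr <- applicable_threshold(age_years, policy)
  if (inherits(metrics, "weekly_metrics")) {
    if (isTRUE(metrics$insufficient)) {
      return(structure(as.integer(prior_tib_min), branch = "insufficient",
                       threshold_applied_pct = thr))
    }
    se <- metrics$sleep_efficiency_pct
  } else {
    se <- as.numeric(metrics)
  }
  step <- policy$step_min
  if (se >= thr && unmet_need == "low") {
    tib <- prior_tib_min + step
    branch <- "increase"
  } else if (se < thr - policy$hold_band_pct) {
    tib <- prior_tib_min - step
    branch <- "decrease"
  } else {
    tib <- prior_tib_min
    branch <- "hold"
  }
  tib <- min(max(tib, policy$tib_floor_min), policy$tib_ceiling_min)
  structure(as.integer(tib), branch = branch, threshold_applied_pct = thr)
}

#' Initial time-in-bed recommendation
#'
#' The first restriction week starts from the prior week's average total
#' sleep time, rounded up to the step grid and clamped to the policy bounds.
#'
#' @param avg_tst_min Prior week's average total sleep time, minutes.
#' @param policy A [titration_policy()].
#' @return Integer minutes on the step grid.
#' @export
initial_tib <- function(avg_tst_min, policy = titration_policy()) {
  tib <- as.integer(ceiling(avg_tst_min / policy$step_min) * policy$step_min)
  min(max(tib, policy$tib_floor_min), policy$tib_ceiling_min)
}

#' Build the weekly personalized sleep plan
#'
#' The user picks a target wake time; the target bedtime is the wake time
#' minus the recommended time in bed, modulo 24 h (so a 420-min TIB with a
#' 06:30 wake gives a 23:30 bedtime).
#'
#' @param week_index Protocol week (1-7).
#' @param target_wake_time Clock time ("HH:MM" or minutes since midnight).
#' @param recommended_tib_min Recommended time in bed, minutes, on the step
#'   grid and within policy bounds.
#' @param policy A [titration_policy()].
#' @param threshold_applied_pct Optional record of the SE threshold used by
#'   the titration that produced `recommended_tib_min`.
#' @return A `sleep_plan` object.
#' @examples
#' build_sleep_plan(2, "06:30", 420)
#' @export
build_sleep_plan <- function(week_index, target_wake_time,
                             recommended_tib_min,
                             policy = titration_policy(),
                             threshold_applied_pct = NA_real_) {
  wake <- parse_clock(target_wake_time)
  tib <- as.integer(recommended_tib_min)
  if (tib %% policy$step_min != 0) {
    dcbti_error(sprintf("recommended_tib_min %d is off the %d-min grid",
                        tib, policy$step_min), "dcbti_config_error")
  }
  if (tib < policy$tib_floor_min || tib > policy$tib_ceiling_min) {
    dcbti_error(sprintf("recommended_tib_min %d outside [%d, %d]",
                        tib, policy$tib_floor_min, policy$tib_ceiling_min),
                "dcbti_config_error")
  }
  structure(
    list(week_index = as.integer(week_index),
         target_wake_time = wake,
         recommended_tib_min = tib,
         target_bedtime = (wake - tib) %% 1440L,
         threshold_applied_pct = threshold_applied_pct),
    class = "sleep_plan"
  )
}

#' @export
print.sleep_plan <- function(x, ...) {
  cat(sprintf(
    "<sleep_plan> week %d: bed %s, wake %s (%d min in bed)\n",
    x$week_index, format_clock(x$target_bedtime),
    format_clock(x$target_wake_time), x$recommended_tib_min))
  invisible(x)
}

#' Just-in-time notification schedule for a sleep plan
#'
#' Daily prompt anchors: at the target wake time, at configurable
#' late-morning and early-afternoon clock times, and at 3 h and 1 h before
#' the target bedtime (computed modulo 24 h, so a 00:30 bedtime anchors the
#' 3-h prompt at 21:30). The 1-h-before anchor carries the wind-down flag:
#' screens off, relaxation on.
#'
#' @param plan A [build_sleep_plan()] result.
#' @param policy A [titration_policy()] supplying the daytime anchors.
#' @return A `notification_schedule` data frame with columns `label`,
#'   `time_min`, `time`, `wind_down`.
#' @examples
#' jit_notification_schedule(build_sleep_plan(2, "06:30", 420))
#' @export
jit_notification_schedule <- function(plan, policy = titration_policy()) {
  bt <- plan$target_bedtime
  sched <- data.frame(
    label = c("post_wake", "late_morning", "early_afternoon",
              "pre_bed_3h", "pre_bed_1h"),
    time_min = c(plan$target_wake_time, policy$late_morning,
                 policy$early_afternoon,
                 (bt - 180L) %% 1440L, (bt - 60L) %% 1440L),
    stringsAsFactors = FALSE
  )
  sched$time <- format_clock(sched$time_min)
  sched$wind_down <- sched$label == "pre_bed_1h"
  class(sched) <- c("notification_schedule", "data.frame")
  sched
}
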