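#' Simulation parameters for a synthetic 7-week cohort
#'
#' Defaults emulate the study conditions of a 30-person, single-arm, 7-week
#' app-delivered CBT-I cohort: baseline insomnia severity distributed
#' N(18.5, 4.6) truncated to 9-26, near-complete daily engagement (0.98 per
#' day), and baseline prescription/OTC sleep-medication use of 23%/47%.
#' Each participant carries a latent nightly sleep need, an arousal level
#' that inflates sleep-onset latency and nighttime wakefulness, and habitual
#' bed habits that leave roughly 100 excess minutes in bed; sleep
#' restriction shrinks arousal by `response_rate` per restricted week, and
#' week-7 severity follows a declared monotone link in sleep-efficiency gain
#' and arousal reduction.
#'
#' @param n_participants Cohort size.
#' @param baseline_isi_mean,baseline_isi_sd Target mean/SD of the truncated
#'   baseline ISI distribution.
#' @param isi_range Inclusive bounds on baseline ISI totals.
#' @param sleep_need_mean,sleep_need_sd Latent nightly sleep need, minutes.
#' @param arousal_mean,arousal_sd Latent arousal scale (1 = typical insomnia
#'   presentation; 0 = no hyperarousal).
#' @param habitual_tib_excess_mean,habitual_tib_excess_sd Habitual time in
#'   bed beyond the latent need, minutes.
#' @param response_rate Fractional reduction of arousal per week spent under
#'   active restriction (recommended TIB within `restriction_margin_min` of
#'   the latent need).
#' @param restriction_margin_min Margin (minutes) above the latent need
#'   within which restriction counts as active.
#' @param engagement_prob Daily probability of app interaction (and diary
#'   completion).
#' @param dropout_prob Per-participant probability of failing to complete
#'   week-7 data collection.
#' @param rx_use_prob,otc_use_prob Baseline medication-use probabilities.
#' @param rx_discontinue_prob,otc_discontinue_prob Probability an improver
#'   (week-7 ISI below `med_improvement_isi_cutoff`) stops the medication.
#' @param med_improvement_isi_cutoff ISI total below which discontinuation
#'   becomes possible.
#' @param isi_link_se,isi_link_arousal,isi_link_noise_sd Week-7 ISI link:
#'   `ISI7 = clamp(round(ISI0 - se_coef * se_gain -
#'   arousal_coef * (arousal0 - arousal7) + noise), 0, 28)`, where `se_gain`
#'   is the arousal-attributable sleep-efficiency gain — the observed week-7
#'   SE minus the SE expected at the realized week-7 time in bed had arousal
#'   stayed at baseline. The link is monotone in observed week-7 SE, and a
#'   zero `response_rate` yields a null effect in expectation.
#' @param dbas_baseline_mean,dbas_baseline_sd,dbas_isi_cor Baseline DBAS-16
#'   total distribution and its correlation with baseline ISI.
#' @param satisfaction_prob,recommend_prob,usefulness_prob_range Week-7
#'   acceptability-response probabilities (per-feature usefulness
#'   probabilities are spaced across the range).
#' @param adherence_noise_sd SD (minutes) of nightly deviation from the
#'   recommended time in bed.
#' @param enrollment_date Shared enrollment date (protocol day 0).
#' @param seed Integer seed; every simulator entry point is deterministic
#'   given the seed.
#' @return A `sim_params` list.
#' @examples
#' sim_params(seed = 1)
#' @export
sim_params <- function(n_participants = 30,
                       baseline_isi_mean = 18.5,
                       baseline_isi_sd = 4.6,
                       isi_range = c(9, 26),
                       sleep_need_mean = 400,
                       sleep_need_sd = 40,
                       arousal_mean = 1,
                       arousal_sd = 0.25,
                       habitual_tib_excess_mean = 100,
                       habitual_tib_excess_sd = 30,
                       response_rate = 0.24,
                       restriction_margin_min = 60,
                       engagement_prob = 0.98,
                       dropout_prob = 0,
                       rx_use_prob = 0.23,
                       otc_use_prob = 0.47,
                       rx_discontinue_prob = 0.85,
                       otc_discontinue_prob = 0.40,
                       med_improvement_isi_cutoff = 15,
                       isi_link_se = 0.4,
                       isi_link_arousal = 4.5,
                       isi_link_noise_sd = 2,
                       dbas_baseline_mean = 47,
                       dbas_baseline_sd = 10.8,
                       dbas_isi_cor = 0.574,
                       satisfaction_prob = 0.90,
                       recommend_prob = 0.93,
                       usefulness_prob_range = c(0.80, 0.93),
                       adherence_noise_sd = 15,
                       enrollment_date = as.Date("2022-01-03"),
                       seed = NULL) {
  p <- as.list(environment())
  probs <- c(p$engagement_prob, p$dropout_prob, p$rx_use_prob, p$otc_use_prob,
             p$rx_discontinue_prob, p$otc_discontinue_prob, p$response_rate,
             p$satisfaction_prob, p$recommend_prob, p$usefulness_prob_range)
  if (any(probs < 0 | probs > 1)) {
    dcbti_error("probabilities must lie in [0, 1]", "dcbti_config_error")
  }
  if (p$baseline_isi_sd <= 0 || p$sleep_need_sd <= 0) {
    dcbti_error("standard deviations must be positive", "dcbti_config_error")
  }
  if (p$isi_range[1] < 0 || p$isi_range[2] > 28 ||
      p$isi_range[1] >= p$isi_range[2]) {
    dcbti_error("isi_range must be an increasing pair within [0, 28]",
                "dcbti_config_error")
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_params> n=%d, baseline ISI ~ truncN(%.1f, %.1f) on [%g, %g],\n",
           "  engagement %.2f/day, response rate %.2f/restricted week, seed %s\n"),
    x$n_participants, x$baseline_isi_mean, x$baseline_isi_sd,
    x$isi_range[1], x$isi_range[2], x$engagement_prob, x$response_rate,
    x$seed %||% "unset"))
  invisible(x)
}

# Truncated-normal sampler calibrated so the *truncated* distribution has the
# requested mean: the latent location is solved by uniroot on the analytic
# truncated-normal mean (truncation to an asymmetric range would otherwise
# shift the realized mean away from the target).
rtrunc_norm_calibrated <- function(n, target_mean, sd, lower, upper) {
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd
    b <- (upper - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    if (z < 1e-12) return(NA_real_)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  if (is.na(trunc_mean(target_mean))) {
    dcbti_error("truncation range carries essentially no probability mass",
                "dcbti_config_error")
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - target_mean,
                       interval = target_mean + c(-4, 4) * sd,
                       extendInt = "yes")$root
  a <- stats::pnorm((lower - mu) / sd)
  b <- stats::pnorm((upper - mu) / sd)
  stats::qnorm(stats::runif(n, a, b)) * sd + mu
}

# Spread an integer total across items, each in [0, item_max], sum-exact.
distribute_items <- function(total, n_items, item_max) {
  total <- as.integer(round(total))
  total <- max(0L, min(total, n_items * item_max))
  items <- rep(total %/% n_items, n_items)
  rem <- total - sum(items)
  if (rem > 0) {
    bump <- sample.int(n_items, rem)
    items[bump] <- items[bump] + 1L
  }
  # random mass moves to roughen the profile without changing the sum
  for (k in seq_len(2L * n_items)) {
    ij <- sample.int(n_items, 2)
    if (items[ij[1]] < item_max && items[ij[2]] > 0) {
      items[ij[1]] <- items[ij[1]] + 1L
      items[ij[2]] <- items[ij[2]] - 1L
    }
  }
  items
}

clampi <- function(x, lo, hi) as.integer(pmin(pmax(round(x), lo), hi))

# Latent participant states; callers are responsible for seeding.
make_states <- function(params) {
  n <- params$n_participants
  isi0 <- clampi(rtrunc_norm_calibrated(n, params$baseline_isi_mean,
                                        params$baseline_isi_sd,
                                        params$isi_range[1],
                                        params$isi_range[2]),
                 params$isi_range[1], params$isi_range[2])
  z_isi <- (isi0 - params$baseline_isi_mean) / params$baseline_isi_sd
  rho <- params$dbas_isi_cor
  dbas0 <- clampi(params$dbas_baseline_mean + params$dbas_baseline_sd *
                    (rho * z_isi + sqrt(1 - rho^2) * stats::rnorm(n)),
                  0, 160)
  need <- clampi(stats::rnorm(n, params$sleep_need_mean,
                              params$sleep_need_sd), 300, 540)
  arousal <- pmin(pmax(stats::rnorm(n, params$arousal_mean,
                                    params$arousal_sd), 0.3), 1.8)
  excess <- clampi(stats::rnorm(n, params$habitual_tib_excess_mean,
                                params$habitual_tib_excess_sd), 40, 180)
  list(
    participant_id = sprintf("P%02d", seq_len(n)),
    age = clampi(stats::rnorm(n, 54, 9.1), 25, 85),
    isi0 = isi0, dbas0 = dbas0,
    sleep_need = need, arousal0 = arousal,
    habitual_tib = need + excess,
    habitual_wake = clampi(390 + stats::rnorm(n, 0, 30), 300, 510) %/% 15L * 15L,
    rx0 = stats::runif(n) < params$rx_use_prob,
    otc0 = stats::runif(n) < params$otc_use_prob,
    completed = stats::runif(n) >= params$dropout_prob
  )
}

#' Simulate one night's diary entry
#'
#' Time in bed follows the active sleep plan with nightly adherence noise
#' (or habitual habits when no plan is active); sleep-onset latency, wake
#' after sleep onset and terminal wakefulness are drawn from arousal-scaled
#' distributions; sleep is capped at the night's latent need, with any
#' surplus time in bed spent awake. The returned entry always satisfies the
#' diary invariants. Uses the current RNG stream; seed upstream for
#' reproducibility.
#'
#' @param state List with `sleep_need` (minutes), `arousal` (nonnegative
#'   scale), `habitual_tib`, `habitual_wake` (minutes since midnight).
#' @param plan A [build_sleep_plan()] result, or `NULL` for habitual sleep.
#' @param participant_id,date Identifiers stamped on the entry.
#' @param adherence_noise_sd Nightly SD around the recommended TIB, minutes.
#' @return A [diary_entry()].
#' @export
simulate_night <- function(state, plan = NULL, participant_id = "P01",
                           date = Sys.Date(), adherence_noise_sd = 15) {
  if (is.null(plan)) {
    tib <- state$habitual_tib + round(stats::rnorm(1, 0, 20))
    wake <- state$habitual_wake + sample(-20:20, 1)
  } else {
    tib <- plan$recommended_tib_min +
      round(stats::rnorm(1, 0, adherence_noise_sd))
    wake <- plan$target_wake_time + sample(-10:10, 1)
  }
  tib <- clampi(tib, 240, 720)
  wake <- as.integer(wake) %% 1440L
  a <- state$arousal
  try_delay <- sample(0:10, 1)
  sol <- as.integer(round(stats::rgamma(1, shape = 2, scale = 17.5 * a)))
  waso <- as.integer(round(stats::rgamma(1, shape = 2, scale = 20 * a)))
  terminal <- as.integer(round(stats::rexp(1, rate = 1 / max(10 * a, 1))))
  awakenings <- stats::rpois(1, 0.8 + 1.5 * a)
  night_need <- clampi(state$sleep_need + stats::rnorm(1, 0, 15), 240, 600)

  budget <- tib - try_delay
  wake_mid <- sol + waso + terminal
  if (wake_mid > budget) {  # pathological draw: scale wakefulness into budget
    f <- budget / wake_mid
    sol <- as.integer(floor(sol * f))
    waso <- as.integer(floor(waso * f))
    terminal <- as.integer(floor(terminal * f))
  }
  available <- budget - sol - waso - terminal
  if (available > night_need) {  # cannot sleep past the need: surplus is WASO
    waso <- waso + (available - night_need)
  }
  if (awakenings == 0 && waso > 0) awakenings <- 1L

  bed <- (wake - tib) %% 1440L
  diary_entry(
    participant_id = participant_id, date = date,
    bedtime = bed,
    try_to_sleep_time = (bed + try_delay) %% 1440L,
    sol_min = sol, awakenings = awakenings, waso_min = waso,
    final_wake_time = (wake - terminal) %% 1440L,
    out_of_bed_time = wake
  )
}

# Weekly sleep-needs item draws from arousal and realized sleep debt.
draw_sleep_needs_items <- function(arousal, debt_frac) {
  latent <- 1.2 * arousal + 4 * debt_frac
  clampi(latent + stats::rnorm(4, 0, 0.5), 0, 4)
}

#' Run the full 7-week closed intervention loop
#'
#' Week 1 is observational (sleep-hygiene education; habitual sleep). From
#' week 2 the plan loop is active: the prior week's diary is aggregated, the
#' first restriction week starts at the prior week's average sleep time
#' rounded up to the 15-min grid, and subsequent weeks titrate via
#' [titrate_time_in_bed()] using the prior week's pooled sleep efficiency
#' and reported unmet sleep need. Arousal decays by `response_rate` for each
#' week spent under active restriction; week-7 insomnia severity is
#' regenerated from the participant's baseline score through the declared
#' monotone link in sleep-efficiency gain and arousal reduction, and
#' medication flags update among improvers. Engagement days are drawn
#' i.i.d. per day; diary entries exist only for engaged days.
#'
#' @param params A [sim_params()]; `params$seed` (or the `seed` argument)
#'   makes the whole trial deterministic.
#' @param policy A [titration_policy()].
#' @param weeks Number of protocol weeks (default 7).
#' @param seed Optional override of `params$seed`.
#' @return A [cohort_dataset()] carrying diaries, instrument responses,
#'   engagement, medication, acceptability and plan tables, with the weekly
#'   sleep-efficiency trajectory in `attr(, "weekly_se")` (participants x
#'   weeks) and latent states in `attr(, "states")`.
#' @examples
#' ds <- run_trial(sim_params(n_participants = 4, seed = 7))
#' summary(ds)
#' @export
run_trial <- function(params = sim_params(), policy = titration_policy(),
                      weeks = 7, seed = NULL) {
  seed <- seed %||% params$seed
  if (!is.null(seed)) set.seed(seed)
  st <- make_states(params)
  n <- params$n_participants
  enroll <- as.Date(params$enrollment_date)

  diaries <- list()
  eng_id <- list(); eng_date <- list()
  sn <- list(); plan_rows <- list()
  weekly_se <- matrix(NA_real_, n, weeks)
  isi7 <- integer(n); dbas7 <- integer(n)
  rx7 <- logical(n); otc7 <- logical(n)

  for (i in seq_len(n)) {
    state <- list(sleep_need = st$sleep_need[i], arousal = st$arousal0[i],
                  habitual_tib = st$habitual_tib[i],
                  habitual_wake = st$habitual_wake[i])
    plan <- NULL
    prior_tib <- NA_integer_
    unmet <- "high"
    last_avg_tib <- NA_real_
    for (w in seq_len(weeks)) {
      days <- which(stats::runif(7) < params$engagement_prob)
      week_dates <- enroll + (w - 1L) * 7L + 0:6
      entries <- lapply(days, function(d) {
        simulate_night(state, plan, st$participant_id[i], week_dates[d],
                       params$adherence_noise_sd)
      })
      if (length(days)) {
        eng_id[[length(eng_id) + 1L]] <- rep(st$participant_id[i],
                                             length(days))
        eng_date[[length(eng_date) + 1L]] <- as.character(week_dates[days])
        diaries <- c(diaries, entries)
      }
      metrics <- aggregate_week(entries, min_days = 3, week_index = w)
      weekly_se[i, w] <- metrics$sleep_efficiency_pct
      if (w == weeks && !is.na(metrics$avg_tib_min)) {
        last_avg_tib <- metrics$avg_tib_min
      }

      debt <- if (metrics$insufficient || is.na(metrics$avg_tst_min)) 0.15 else
        max(0, 1 - metrics$avg_tst_min / state$sleep_need)
      sn_items <- draw_sleep_needs_items(state$arousal, debt)
      unmet <- score_sleep_needs(sn_items)
      sn[[length(sn) + 1L]] <- c(i = i, w = w, sn_items)

      if (w < weeks) {
        if (is.na(prior_tib)) {
          base_tst <- if (metrics$insufficient || is.na(metrics$avg_tst_min))
            state$sleep_need else metrics$avg_tst_min
          tib_next <- initial_tib(base_tst, policy)
          branch <- "initial"
        } else {
          tib_next <- titrate_time_in_bed(metrics, unmet, st$age[i],
                                          prior_tib, policy)
          branch <- attr(tib_next, "branch")
        }
        plan <- build_sleep_plan(w + 1L, state$habitual_wake,
                                 as.integer(tib_next), policy,
                                 applicable_threshold(st$age[i], policy))
        plan_rows[[length(plan_rows) + 1L]] <- list(
          id = st$participant_id[i], week = w + 1L,
          wake = plan$target_wake_time, tib = plan$recommended_tib_min,
          bed = plan$target_bedtime, branch = branch)
        prior_tib <- as.integer(tib_next)
        if (tib_next <= state$sleep_need + params$restriction_margin_min) {
          state$arousal <- state$arousal * (1 - params$response_rate)
        }
      }
    }
    se7 <- weekly_se[i, weeks]
    tib7 <- if (!is.na(last_avg_tib)) last_avg_tib else
      state$habitual_tib
    # arousal-attributable SE gain: observed week-7 SE minus the SE expected
    # at the realized week-7 TIB had arousal stayed at baseline (expected
    # nightly wakefulness under the night model is ~5 + 85 * arousal min)
    se_cf <- 100 * max(min(tib7 - (5 + 85 * st$arousal0[i]),
                           state$sleep_need), 0) / tib7
    se_gain <- if (is.na(se7)) 0 else se7 - se_cf
    arousal_drop <- st$arousal0[i] - state$arousal
    isi7[i] <- clampi(st$isi0[i] - params$isi_link_se * se_gain -
                        params$isi_link_arousal * arousal_drop +
                        stats::rnorm(1, 0, params$isi_link_noise_sd), 0, 28)
    dbas7[i] <- clampi(st$dbas0[i] - (11 / 8.1) * (st$isi0[i] - isi7[i]) +
                         stats::rnorm(1, 0, 3), 0, 160)
    improved <- isi7[i] < params$med_improvement_isi_cutoff
    rx7[i] <- st$rx0[i] &&
      !(improved && stats::runif(1) < params$rx_discontinue_prob)
    otc7[i] <- st$otc0[i] &&
      !(improved && stats::runif(1) < params$otc_discontinue_prob)
  }

  isi_items <- rbind(
    instrument_rows(st$participant_id, "baseline", st$isi0, 7L, 4L),
    instrument_rows(st$participant_id, "week7", isi7, 7L, 4L))
  dbas_items <- rbind(
    instrument_rows(st$participant_id, "baseline", st$dbas0, 16L, 10L),
    instrument_rows(st$participant_id, "week7", dbas7, 16L, 10L))

  accept <- simulate_acceptability(st$participant_id, params)

  meds <- rbind(
    data.frame(participant_id = st$participant_id, timepoint = "baseline",
               prescription = st$rx0, otc = st$otc0,
               stringsAsFactors = FALSE),
    data.frame(participant_id = st$participant_id, timepoint = "week7",
               prescription = rx7, otc = otc7, stringsAsFactors = FALSE))

  # incomplete participants contribute no week-7 assessments
  if (any(!st$completed)) {
    drop_ids <- st$participant_id[!st$completed]
    isi_items <- isi_items[!(isi_items$timepoint == "week7" &
                               isi_items$participant_id %in% drop_ids), ]
    dbas_items <- dbas_items[!(dbas_items$timepoint == "week7" &
                                 dbas_items$participant_id %in% drop_ids), ]
    meds <- meds[!(meds$timepoint == "week7" &
                     meds$participant_id %in% drop_ids), ]
    accept <- accept[!accept$participant_id %in% drop_ids, ]
  }

  sn_m <- do.call(rbind, sn)
  sleep_needs_tbl <- data.frame(
    participant_id = st$participant_id[sn_m[, 1]], week = sn_m[, 2],
    item1 = sn_m[, 3], item2 = sn_m[, 4], item3 = sn_m[, 5],
    item4 = sn_m[, 6], stringsAsFactors = FALSE)
  plans_tbl <- if (length(plan_rows)) data.frame(
    participant_id = vapply(plan_rows, `[[`, character(1), "id"),
    week = vapply(plan_rows, `[[`, integer(1), "week"),
    target_wake_time = format_clock(vapply(plan_rows, `[[`, integer(1),
                                           "wake")),
    recommended_tib_min = vapply(plan_rows, `[[`, integer(1), "tib"),
    target_bedtime = format_clock(vapply(plan_rows, `[[`, integer(1),
                                         "bed")),
    branch = vapply(plan_rows, `[[`, character(1), "branch"),
    stringsAsFactors = FALSE) else NULL
  engagement_tbl <- if (length(eng_id)) data.frame(
    participant_id = unlist(eng_id), date = unlist(eng_date),
    stringsAsFactors = FALSE) else NULL

  ds <- cohort_dataset(
    participants = data.frame(
      participant_id = st$participant_id, age = st$age,
      enrollment_date = as.character(enroll),
      completed = st$completed, stringsAsFactors = FALSE),
    diaries = diary_table(diaries),
    isi = isi_items, dbas = dbas_items,
    sleep_needs = sleep_needs_tbl,
    engagement = engagement_tbl,
    medications = meds, acceptability = accept,
    plans = plans_tbl,
    provenance = list(schema_version = dataset_schema_version,
                      seed = seed %||% NA, generator = "run_trial")
  )
  attr(ds, "weekly_se") <- weekly_se
  attr(ds, "states") <- st
  ds
}

#' Generate a baseline synthetic cohort
#'
#' Draws participant latents and baseline assessments and simulates the
#' first (pre-plan) diary week. Equivalent to the state a trial is in before
#' the plan loop starts. Deterministic given `params$seed`.
#'
#' @param params A [sim_params()].
#' @return A [cohort_dataset()] with week-1 diaries, baseline ISI/DBAS
#'   items, week-1 engagement and baseline medication flags; baseline ISI
#'   totals in `attr(, "states")$isi0`.
#' @examples
#' ds <- generate_cohort(sim_params(n_participants = 5, seed = 1))
#' @export
generate_cohort <- function(params = sim_params()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  st <- make_states(params)
  n <- params$n_participants
  enroll <- as.Date(params$enrollment_date)
  diaries <- list()
  eng_id <- list(); eng_date <- list()
  for (i in seq_len(n)) {
    state <- list(sleep_need = st$sleep_need[i], arousal = st$arousal0[i],
                  habitual_tib = st$habitual_tib[i],
                  habitual_wake = st$habitual_wake[i])
    days <- which(stats::runif(7) < params$engagement_prob)
    if (!length(days)) next
    dates <- enroll + 0:6
    entries <- lapply(days, function(d) {
      simulate_night(state, NULL, st$participant_id[i], dates[d],
                     params$adherence_noise_sd)
    })
    eng_id[[length(eng_id) + 1L]] <- rep(st$participant_id[i], length(days))
    eng_date[[length(eng_date) + 1L]] <- as.character(dates[days])
    diaries <- c(diaries, entries)
  }
  ds <- cohort_dataset(
    participants = data.frame(
      participant_id = st$participant_id, age = st$age,
      enrollment_date = as.character(enroll),
      completed = st$completed, stringsAsFactors = FALSE),
    diaries = diary_table(diaries),
    isi = instrument_rows(st$participant_id, "baseline", st$isi0, 7L, 4L),
    dbas = instrument_rows(st$participant_id, "baseline", st$dbas0, 16L, 10L),
    sleep_needs = empty_sleep_needs(),
    engagement = if (length(eng_id)) data.frame(
      participant_id = unlist(eng_id), date = unlist(eng_date),
      stringsAsFactors = FALSE) else NULL,
    medications = data.frame(
      participant_id = st$participant_id, timepoint = "baseline",
      prescription = st$rx0, otc = st$otc0, stringsAsFactors = FALSE),
    acceptability = empty_acceptability(),
    plans = empty_plans(),
    provenance = list(schema_version = dataset_schema_version,
                      seed = params$seed %||% NA,
                      generator = "generate_cohort")
  )
  attr(ds, "states") <- st
  ds
}

# Vectorized conversion of a diary_entry list to the diaries table schema.
diary_table <- function(entries) {
  if (!length(entries)) return(NULL)
  g <- function(field, type) vapply(entries, `[[`, type, field)
  data.frame(
    participant_id = g("participant_id", character(1)),
    date = as.character(as.Date(g("date", numeric(1)),
                                origin = "1970-01-01")),
    bedtime = format_clock(g("bedtime", integer(1))),
    try_to_sleep_time = format_clock(g("try_to_sleep_time", integer(1))),
    sol_min = g("sol_min", integer(1)),
    awakenings = g("awakenings", integer(1)),
    waso_min = g("waso_min", integer(1)),
    final_wake_time = format_clock(g("final_wake_time", integer(1))),
    out_of_bed_time = format_clock(g("out_of_bed_time", integer(1))),
    stringsAsFactors = FALSE
  )
}

instrument_rows <- function(ids, timepoint, totals, n_items, item_max) {
  items <- t(vapply(totals, distribute_items, integer(n_items),
                    n_items = n_items, item_max = item_max))
  df <- data.frame(participant_id = ids, timepoint = timepoint,
                   stringsAsFactors = FALSE)
  for (j in seq_len(n_items)) df[[paste0("item", j)]] <- items[, j]
  df
}

simulate_acceptability <- function(ids, params) {
  n <- length(ids)
  p_feat <- seq(params$usefulness_prob_range[1],
                params$usefulness_prob_range[2], length.out = 10)
  df <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (j in 1:10) {
    useful <- stats::runif(n) < p_feat[j]
    df[[paste0("feature", j)]] <- ifelse(
      useful, sample(2:4, n, replace = TRUE, prob = c(0.2, 0.4, 0.4)), 1L)
  }
  df$satisfaction <- ifelse(stats::runif(n) < params$satisfaction_prob,
                            sample(4:5, n, replace = TRUE),
                            sample(1:3, n, replace = TRUE))
  df$recommend <- ifelse(stats::runif(n) < params$recommend_prob,
                         sample(4:5, n, replace = TRUE),
                         sample(1:3, n, replace = TRUE))
  df
}
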