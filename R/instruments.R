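#' Score the Insomnia Severity Index
#'
#' Seven items, each rated 0-4; the total (0-28) falls into one of four
#' clinical bands: no clinical insomnia (0-7), mild sleep disturbance (8-14),
#' moderate insomnia (15-21), severe insomnia (22-28). Missing or
#' out-of-range items are rejected; no imputation is performed.
#'
#' @param items Integer vector of 7 item responses in 0-4.
#' @return An `isi_score` list: `total`, `band`.
#' @examples
#' score_isi(c(3, 3, 2, 3, 3, 2, 2))
#' @export
score_isi <- function(items) {
  items <- as.numeric(items)
  if (length(items) != 7 || anyNA(items) ||
      any(items < 0 | items > 4 | items != floor(items))) {
    dcbti_error("ISI requires exactly 7 complete integer items in 0-4",
                "dcbti_invalid_response")
  }
  total <- as.integer(sum(items))
  structure(list(total = total, band = isi_band(total)),
            class = "isi_score")
}

#' @export
print.isi_score <- function(x, ...) {
  cat(sprintf("<isi_score> total %d (%s)\n", x$total, x$band))
  invisible(x)
}

#' ISI clinical band for a total score
#'
#' @param total Integer total(s) in 0-28.
#' @return Factor with levels `none`, `mild`, `moderate`, `severe`.
#' @export
isi_band <- function(total) {
  total <- as.numeric(total)
  if (anyNA(total) || any(total < 0 | total > 28 | total != floor(total))) {
    dcbti_error("ISI totals must be integers in 0-28",
                "dcbti_invalid_response")
  }
  levels <- c("none", "mild", "moderate", "severe")
  factor(levels[findInterval(total, c(0, 8, 15, 22))], levels = levels)
}

# Standard DBAS-16 subscale membership, kept as metadata alongside item-level
# belief prioritization.
dbas16_subscales <- c(
  "expectations", "expectations", "worry_helplessness", "worry_helplessness",
  "consequences", "medication", "consequences", "worry_helplessness",
  "consequences", "worry_helplessness", "worry_helplessness", "consequences",
  "medication", "worry_helplessness", "medication", "consequences"
)

#' Score the brief DBAS-16
#'
#' Sixteen statements about sleep rated on a configurable agreement scale
#' (default 0-10). The total is the item sum; items are also ranked so the
#' respondent's most strongly endorsed dysfunctional beliefs can be targeted
#' for cognitive reframing.
#'
#' @param items Numeric vector of 16 item responses in `[0, scale_max]`.
#' @param scale_max Maximum of the response scale (default 10).
#' @return A `dbas_score` list: `total`, `items`, `ranking` (item indices in
#'   descending endorsement, ties by ascending index), `subscale` metadata.
#' @examples
#' score_dbas(rep(5, 16))
#' @export
score_dbas <- function(items, scale_max = 10) {
  items <- as.numeric(items)
  if (length(items) != 16 || anyNA(items) ||
      any(items < 0 | items > scale_max)) {
    dcbti_error(sprintf(
      "DBAS-16 requires exactly 16 complete items in [0, %g]", scale_max),
      "dcbti_invalid_response")
  }
  structure(
    list(total = sum(items), items = items,
         ranking = order(-items, seq_along(items)),
         subscale = dbas16_subscales, scale_max = scale_max),
    class = "dbas_score"
  )
}

#' @export
print.dbas_score <- function(x, ...) {
  cat(sprintf("<dbas_score> total %g (16 items, 0-%g scale); top beliefs: %s\n",
              x$total, x$scale_max,
              paste(top_dysfunctional_beliefs(x), collapse = ", ")))
  invisible(x)
}

#' Most prominent dysfunctional beliefs
#'
#' The `k` highest-scoring DBAS-16 items, ties broken by ascending item index
#' so prioritization is deterministic. These are the beliefs the program
#' pairs with alternative thoughts.
#'
#' @param score A [score_dbas()] result.
#' @param k Number of beliefs to return (default 3).
#' @return Integer item indices, strongest first.
#' @export
top_dysfunctional_beliefs <- function(score, k = 3) {
  if (!inherits(score, "dbas_score")) {
    dcbti_error("score must be a dbas_score", "dcbti_invalid_response")
  }
  if (k > length(score$items)) {
    dcbti_error("k exceeds the number of DBAS items",
                "dcbti_invalid_response")
  }
  score$ranking[seq_len(k)]
}

#' Score the weekly sleep-needs assessment
#'
#' Four daytime-consequence ratings (tired/fatigued, sleepy/drowsy, napping
#' or dozing, inadequate-sleep feeling; each 0-4). The unmet-need level is
#' low when the item mean falls below `cutoff`, high otherwise (a mean
#' exactly at the cutoff is high). Only a low unmet need allows the titration
#' to extend time in bed.
#'
#' @param items Numeric vector of 4 ratings in 0-4.
#' @param cutoff Item-mean cutoff (default 1.5).
#' @return `"low"` or `"high"`.
#' @examples
#' score_sleep_needs(c(1, 2, 1, 2))  # mean 1.5 -> "high"
#' @export
score_sleep_needs <- function(items, cutoff = 1.5) {
  items <- as.numeric(items)
  if (length(items) != 4 || anyNA(items) || any(items < 0 | items > 4)) {
    dcbti_error("sleep-needs assessment requires 4 complete items in 0-4",
                "dcbti_invalid_response")
  }
  if (mean(items) < cutoff) "low" else "high"
}

#' Screening form for trial eligibility
#'
#' Captures the intake screen: demographics, treatment history, sleep
#' complaint duration and frequency, a 5-symptom apnea screen, and the
#' exclusion flags.
#'
#' @param age_years Age in years.
#' @param cancer_type One of `"breast"`, `"prostate"`, `"colon"`, or other.
#' @param months_since_treatment Months since completing curative-intent
#'   treatment.
#' @param sleep_problem_nights_per_week Nights per week with trouble falling
#'   or staying asleep.
#' @param sleep_problem_duration_months Duration of the sleep complaint.
#' @param apnea_symptom_count Number of apnea-suggestive symptoms endorsed
#'   (0-5).
#' @param other_sleep_disorder,insomnia_before_cancer,
#'   interfering_physical_symptoms,other_major_condition,active_cancer,
#'   prior_cbti,night_shift Exclusion flags.
#' @param has_compatible_device,internet_access,english_literate,can_consent
#'   Inclusion flags.
#' @return A `screening_form` list.
#' @export
screening_form <- function(age_years,
                           cancer_type = "breast",
                           months_since_treatment,
                           sleep_problem_nights_per_week,
                           sleep_problem_duration_months,
                           apnea_symptom_count = 0,
                           other_sleep_disorder = FALSE,
                           insomnia_before_cancer = FALSE,
                           interfering_physical_symptoms = FALSE,
                           other_major_condition = FALSE,
                           active_cancer = FALSE,
                           prior_cbti = FALSE,
                           night_shift = FALSE,
                           has_compatible_device = TRUE,
                           internet_access = TRUE,
                           english_literate = TRUE,
                           can_consent = TRUE) {
  if (!is_count(apnea_symptom_count) || apnea_symptom_count > 5) {
    dcbti_error("apnea_symptom_count must be an integer in 0-5",
                "dcbti_invalid_response")
  }
  if (months_since_treatment < 0 || sleep_problem_duration_months < 0) {
    dcbti_error("month counts must be nonnegative", "dcbti_invalid_response")
  }
  structure(as.list(environment()), class = "screening_form")
}

#' Apply the eligibility screen
#'
#' A participant is eligible only when every inclusion rule is satisfied
#' (adult; curative treatment completed 3-60 months ago; sleep trouble at
#' least 3 nights per week for at least 3 months; compatible smartphone with
#' internet access; English literacy; consent) and no exclusion is triggered
#' (3 or more apnea-suggestive symptoms; another diagnosed sleep disorder;
#' insomnia predating the cancer diagnosis; interfering physical symptoms;
#' another major condition likely to disturb sleep; active cancer; prior
#' CBT-I; night-shift work). All failed rules are listed; a decision object
#' is always returned.
#'
#' @param form A [screening_form()].
#' @return An `eligibility_decision` list: `eligible` flag and character
#'   vector `reasons` naming every failed rule.
#' @export
screen_eligibility <- function(form) {
  if (!inherits(form, "screening_form")) {
    dcbti_error("form must be a screening_form", "dcbti_invalid_response")
  }
  reasons <- character(0)
  fail <- function(cond, why) if (cond) reasons <<- c(reasons, why)
  fail(form$age_years < 18, "inclusion: under 18 years of age")
  fail(form$months_since_treatment < 3,
       "inclusion: treatment completed less than 3 months ago")
  fail(form$months_since_treatment > 60,
       "inclusion: treatment completed more than 5 years ago")
  fail(form$sleep_problem_nights_per_week < 3,
       "inclusion: sleep trouble fewer than 3 nights per week")
  fail(form$sleep_problem_duration_months < 3,
       "inclusion: sleep trouble for less than 3 months")
  fail(!form$has_compatible_device, "inclusion: no compatible smartphone")
  fail(!form$internet_access, "inclusion: no smartphone internet access")
  fail(!form$english_literate, "inclusion: unable to read and write English")
  fail(!form$can_consent, "inclusion: unable to provide informed consent")
  fail(form$apnea_symptom_count >= 3,
       "exclusion: 3 or more symptoms suggestive of sleep apnea")
  fail(form$other_sleep_disorder,
       "exclusion: diagnosed sleep disorder other than insomnia")
  fail(form$insomnia_before_cancer,
       "exclusion: insomnia diagnosed before cancer")
  fail(form$interfering_physical_symptoms,
       "exclusion: physical symptoms interfering with sleep")
  fail(form$other_major_condition,
       "exclusion: major psychiatric or medical condition")
  fail(form$active_cancer, "exclusion: evidence of active cancer")
  fail(form$prior_cbti, "exclusion: current or previous CBT-I")
  fail(form$night_shift,
       "exclusion: night-shift work or restricted sleep opportunity")
  structure(list(eligible = length(reasons) == 0, reasons = reasons),
            class = "eligibility_decision")
}

#' @export
print.eligibility_decision <- function(x, ...) {
  cat(sprintf("<eligibility_decision> %s\n",
              if (x$eligible) "eligible" else "ineligible"))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Read and score an instrument CSV
#'
#' One row per participant per timepoint with columns `participant_id`,
#' `timepoint`, and `item1..itemN` (N = 7 for ISI, 16 for DBAS, 4 for the
#' sleep-needs assessment).
#'
#' @param path Path to the CSV.
#' @param instrument `"isi"`, `"dbas"` or `"sleepneeds"`.
#' @param ... Passed to the underlying scorer (`scale_max`, `cutoff`).
#' @return Data frame with the id columns plus the scored summary
#'   (`total`/`band` for ISI, `total` and top-belief items for DBAS,
#'   `unmet_need` for sleep needs).
#' @export
score_instrument_csv <- function(path, instrument = c("isi", "dbas",
                                                      "sleepneeds"), ...) {
  instrument <- match.arg(instrument)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  n_items <- switch(instrument, isi = 7L, dbas = 16L, sleepneeds = 4L)
  item_cols <- paste0("item", seq_len(n_items))
  missing <- setdiff(c("participant_id", "timepoint", item_cols), names(df))
  if (length(missing)) {
    dcbti_error(sprintf("instrument CSV missing column(s): %s",
                        paste(missing, collapse = ", ")),
                "dcbti_schema_error")
  }
  out <- df[c("participant_id", "timepoint")]
  for (i in seq_len(nrow(df))) {
    items <- as.numeric(df[i, item_cols])
    scored <- tryCatch(
      switch(instrument,
             isi = score_isi(items),
             dbas = score_dbas(items, ...),
             sleepneeds = list(unmet_need = score_sleep_needs(items, ...))),
      dcbti_error = function(e) {
        dcbti_error(sprintf("line %d: %s", i + 1L, conditionMessage(e)),
                    "dcbti_invalid_response")
      })
    if (instrument == "isi") {
      out$total[i] <- scored$total
      out$band[i] <- as.character(scored$band)
    } else if (instrument == "dbas") {
      out$total[i] <- scored$total
      top <- top_dysfunctional_beliefs(scored)
      out$belief1[i] <- top[1]; out$belief2[i] <- top[2]
      out$belief3[i] <- top[3]
    } else {
      out$unmet_need[i] <- scored$unmet_need
    }
  }
  out
}
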