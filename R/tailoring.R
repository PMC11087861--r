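#' Motivational-interviewing tailoring level
#'
#' Each week the program asks how motivated and how confident the user feels
#' about following the newly presented sleep plan (each 0-10). Encouragement
#' is tailored to three levels per dimension; the default cutpoints map 0-3
#' to low, 4-7 to medium, 8-10 to high, independently for motivation and
#' confidence. The mapping is monotone in each dimension.
#'
#' @param motivation,confidence Integer ratings 0-10.
#' @param cutpoints Two increasing upper bounds: ratings `<= cutpoints[1]`
#'   are low, `<= cutpoints[2]` medium, above high.
#' @return Named character vector `c(motivation = ..., confidence = ...)`
#'   with values `"low"`, `"medium"` or `"high"`.
#' @examples
#' mi_tailoring_level(4, 8)
#' @export
mi_tailoring_level <- function(motivation, confidence, cutpoints = c(3, 7)) {
  for (v in c(motivation, confidence)) {
    if (!is_count(v) || v > 10) {
      dcbti_error("motivation and confidence must be integers in 0-10",
                  "dcbti_invalid_response")
    }
  }
  if (length(cutpoints) != 2 || cutpoints[1] >= cutpoints[2]) {
    dcbti_error("cutpoints must be two increasing values",
                "dcbti_config_error")
  }
  lvl <- function(x) {
    c("low", "medium", "high")[findInterval(x, c(-Inf, cutpoints[1] + 1,
                                                 cutpoints[2] + 1))]
  }
  c(motivation = lvl(motivation), confidence = lvl(confidence))
}

#' Assemble the personal reminder pool
#'
#' Collects the user's selected coping statements and the alternative
#' thoughts they chose for their top dysfunctional beliefs into the pool the
#' notification scheduler draws from. Ordering follows selection order;
#' duplicates are dropped keeping the first occurrence; an alternative
#' thought may only reference a belief in the user's top set. Re-assembling
#' an assembled pool is a no-op (idempotent).
#'
#' @param selected_coping Character vector of coping-statement identifiers
#'   (content-catalog keys), in selection order.
#' @param top_beliefs Identifiers of the user's top dysfunctional beliefs
#'   (e.g. from [top_dysfunctional_beliefs()]).
#' @param selected_thoughts Named character vector or list: names are belief
#'   identifiers (must be in `top_beliefs`), values are alternative-thought
#'   identifiers.
#' @return A `reminder_pool` list: `coping_statements`,
#'   `alternative_thoughts` (named character vector).
#' @examples
#' assemble_reminder_pool(c("cope_natural", "cope_routine", "cope_natural"),
#'                        top_beliefs = c(5, 9, 12),
#'                        selected_thoughts = c("5" = "alt_no_one_amount"))
#' @export
assemble_reminder_pool <- function(selected_coping = character(0),
                                   top_beliefs = character(0),
                                   selected_thoughts = character(0)) {
  thoughts <- unlist(selected_thoughts)
  if (length(thoughts)) {
    keys <- names(thoughts)
    if (is.null(keys) || any(!keys %in% as.character(top_beliefs))) {
      dcbti_error(
        "every alternative thought must be keyed to one of the top beliefs",
        "dcbti_invalid_response")
    }
    thoughts <- thoughts[!duplicated(paste(keys, thoughts))]
  } else {
    thoughts <- stats::setNames(character(0), character(0))
  }
  structure(
    list(coping_statements = unique(as.character(selected_coping)),
         alternative_thoughts = thoughts),
    class = "reminder_pool"
  )
}

#' @export
print.reminder_pool <- function(x, ...) {
  cat(sprintf("<reminder_pool> %d coping statement(s), %d alternative thought(s)\n",
              length(x$coping_statements), length(x$alternative_thoughts)))
  invisible(x)
}

#' Weekly intervention topic schedule
#'
#' The seven-week program unlocks components cumulatively: sleep-hygiene
#' education (week 1), the personalized sleep plan with a daily activity
#' plan (week 2), motivational interviewing for plan adherence (week 3),
#' relaxation techniques (week 4), dysfunctional beliefs about sleep
#' (week 5), maintenance (week 6), and program review (week 7).
#'
#' @return Data frame with columns `week`, `topic`, `components`
#'   (comma-separated component keys active that week).
#' @export
topic_schedule <- function() {
  unlock <- c(sleep_hygiene = 1L, sleep_plan = 2L, daily_activity = 2L,
              motivational_interviewing = 3L, relaxation = 4L,
              dysfunctional_beliefs = 5L, maintenance = 6L, review = 7L)
  topics <- c("sleep_hygiene", "sleep_plan", "motivational_interviewing",
              "relaxation", "dysfunctional_beliefs", "maintenance", "review")
  data.frame(
    week = 1:7,
    topic = topics,
    components = vapply(1:7, function(w) {
      paste(names(unlock)[unlock <= w], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Components unlocked in a given program week
#'
#' @param week Protocol week 1-7.
#' @return Character vector of component keys available that week.
#' @export
components_unlocked <- function(week) {
  if (!is_count(week) || week < 1 || week > 7) {
    dcbti_error("week must be an integer in 1-7", "dcbti_config_error")
  }
  strsplit(topic_schedule()$components[week], ",")[[1]]
}
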