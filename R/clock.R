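#' Clock times as minutes since midnight
#'
#' Diary clock fields (bedtime, wake time, ...) are held as integer minutes
#' since midnight in `[0, 1440)`. Interval lengths are computed modulo 24 h so
#' a bedtime of 23:30 and a rise time of 06:30 span 420 minutes, and averaging
#' is done on an unwrapped axis chosen per field (bedtimes are referenced to
#' 18:00, wake times to midnight) so that a bedtime series straddling midnight
#' averages sensibly.
#'
#' @param x Character vector of "HH:MM" 24-hour times, or numeric minutes.
#' @return Integer vector of minutes since midnight.
#' @examples
#' parse_clock("23:30")
#' format_clock(1410)
#' clock_span(1410, 390)  # 23:30 -> 06:30 across midnight
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) {
    m <- as.integer(x)
    if (any(is.na(m) | m < 0 | m >= 1440)) {
      dcbti_error("clock time must be integer minutes in [0, 1440)",
                  "dcbti_invalid_clock")
    }
    return(m)
  }
  ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x)
  if (any(!ok | is.na(x))) {
    bad <- x[!ok | is.na(x)]
    dcbti_error(sprintf("invalid clock time '%s' (expected HH:MM, 24-hour)",
                        bad[1]), "dcbti_invalid_clock")
  }
  hh <- as.integer(sub(":.*", "", x))
  mm <- as.integer(sub(".*:", "", x))
  hh * 60L + mm
}

#' @rdname parse_clock
#' @param minutes Integer minutes since midnight.
#' @export
format_clock <- function(minutes) {
  m <- as.integer(minutes) %% 1440L
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

#' @rdname parse_clock
#' @param start,end Clock times in minutes since midnight.
#' @export
clock_span <- function(start, end) {
  (as.integer(end) - as.integer(start)) %% 1440L
}

# Unwrap a clock time onto a linear axis anchored at `anchor` minutes, so that
# times up to 24 h after the anchor are monotone. Bedtimes use anchor 18:00
# (1080); wake times use midnight (0).
unwrap_clock <- function(minutes, anchor) {
  anchor + (as.integer(minutes) - anchor) %% 1440L
}

# Mean / sample SD of clock times on the unwrapped axis, wrapped back.
clock_mean <- function(minutes, anchor) {
  u <- unwrap_clock(minutes, anchor)
  as.integer(round(mean(u))) %% 1440L
}

clock_sd <- function(minutes, anchor) {
  if (length(minutes) < 2) return(NA_real_)
  stats::sd(unwrap_clock(minutes, anchor))
}
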