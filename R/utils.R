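#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish validation failures from bugs.
dcbti_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "dcbti_error", "error"),
                      call = call))
}

#' Round half away from zero
#'
#' Rounds to the convention used for every reported percentage: halves go up
#' (29/30 nights adherent is 96.67%, reported as 97), unlike [base::round()]'s
#' round-half-even. Negative inputs round away from zero.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(96.5)   # 97
#' round_half_up(87.45, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percentage of a count over a denominator, whole-percent round-half-up.
pct_of <- function(k, n) round_half_up(100 * k / n)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}

is_flag <- function(x) is.logical(x) && length(x) == 1 && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
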