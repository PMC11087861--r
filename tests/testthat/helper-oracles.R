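# Independent oracles used to freeze expected values. Each takes a route
# through the problem different from the implementation it checks.

# Minute-enumeration oracle for nightly metrics: mark each minute of the bed
# interval asleep/awake and count, instead of doing interval arithmetic.
oracle_night <- function(bed, try_sleep, sol, waso, final_wake, out_bed) {
  to_min <- function(x) {
    hh <- as.integer(sub(":.*", "", x))
    mm <- as.integer(sub(".*:", "", x))
    hh * 60 + mm
  }
  b <- to_min(bed); o <- to_min(out_bed)
  tib <- (o - b) %% 1440
  awake <- logical(tib)  # minute i = interval [b + i - 1, b + i)
  pre <- (to_min(try_sleep) - b) %% 1440 + sol
  if (pre > 0) awake[seq_len(pre)] <- TRUE
  term <- (o - to_min(final_wake)) %% 1440
  if (term > 0) awake[tib - seq_len(term) + 1] <- TRUE
  # WASO minutes placed mid-night (position does not affect totals)
  if (waso > 0) awake[pre + seq_len(waso)] <- TRUE
  tst <- sum(!awake)
  list(tib = tib, tst = tst, se = floor(1000 * tst / tib + 0.5) / 10)
}

# Explicit rule-table oracle for the weekly titration decision.
oracle_titrate <- function(se, unmet, age, prior, floor_min = 300,
                           ceiling_min = 600, step = 15, band = 5) {
  thr <- if (age >= 65) 80 else 85
  out <- if (se >= thr && unmet == "low") {
    prior + step
  } else if (se < thr - band) {
    prior - step
  } else {
    prior
  }
  min(max(out, floor_min), ceiling_min)
}

# Brute-force sum (element-by-element accumulation).
oracle_sum <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s
}

# Pearson correlation from the raw covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- oracle_sum(x * y) - oracle_sum(x) * oracle_sum(y) / n
  sxx <- oracle_sum(x^2) - oracle_sum(x)^2 / n
  syy <- oracle_sum(y^2) - oracle_sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# A plain valid week of identical nights.
make_identical_week <- function(n = 7, participant = "P01") {
  lapply(seq_len(n), function(i) {
    diary_entry(participant, as.Date("2022-01-10") + i - 1,
                "23:00", "23:00", 30, 2, 30, "07:00", "07:00")
  })
}

# Random valid diary entry (used by property tests); seeded by caller.
random_entry <- function(participant = "P01", date = as.Date("2022-01-10")) {
  tib <- sample(300:600, 1)
  wake <- sample(0:1439, 1)
  bed <- (wake - tib) %% 1440
  try_delay <- sample(0:15, 1)
  sol <- sample(0:40, 1)
  waso <- sample(0:40, 1)
  term <- sample(0:20, 1)
  diary_entry(participant, date, bed, (bed + try_delay) %% 1440,
              sol, sample(0:4, 1), waso,
              (wake - term) %% 1440, wake)
}
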