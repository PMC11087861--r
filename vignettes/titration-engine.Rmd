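---
title: "The sleep-restriction titration engine and its synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sleep-restriction titration engine and its synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcbti)
```

## What this package computes

Self-directed digital CBT-I programs replace the weekly clinic visit with
an algorithm: the participant logs each night's sleep, the program
aggregates a week of logs into sleep metrics, and a titration rule moves
the recommended time in bed (TIB) toward a sleep-efficiency target, with
the target bedtime anchored to the participant's chosen wake time. This
package implements that loop end to end — diary arithmetic, titration,
plan and notification construction, instrument scoring, tailoring rules,
and the feasibility statistics a single-arm trial of such a program
reports — together with a seeded simulator that generates whole synthetic
cohorts so the pipeline can be tested without participant data.

## Diary arithmetic

A night is described by seven quantities: bedtime, the time the sleeper
started trying to sleep, sleep-onset latency (SOL), the number of
awakenings, wake after sleep onset (WASO), final wake time, and
out-of-bed time. Time in bed runs from bedtime to out-of-bed — not from
lights-out to final waking — because stimulus control targets total bed
occupancy. Total sleep time removes every reported waking component:

```{r}
e <- diary_entry("P01", "2022-01-10", "22:00", "22:30", sol_min = 60,
                 awakenings = 2, waso_min = 45, final_wake_time = "06:00",
                 out_of_bed_time = "07:00")
derive_entry_metrics(e)
```

All clock arithmetic is modular over 24 h, so nights wrapping midnight
need no special casing; bed intervals longer than 18 h are rejected as
data-entry errors since no plausible night is that long. Sleep efficiency
is reported to 0.1 percentage point; durations are integer minutes.

Weekly sleep efficiency pools minutes (`100 * sum(TST) / sum(TIB)`)
rather than averaging nightly ratios, so long and short nights carry their
actual weight. Bedtime averages and consistency (sample SD in minutes)
are computed on an axis unwrapped at 18:00 — every plausible bedtime falls
within one cycle of that anchor — and wake times on an axis unwrapped at
midnight. Linear SD on the unwrapped axis was chosen over circular
statistics: it is simple, monotone in spread, and adequate for times
anchored to a single evening. Weeks with fewer than `min_days = 3` logged
nights are flagged insufficient and never drive a plan update.

## The titration rule

```{r}
titration_policy()
```

The decision uses the prior week's pooled sleep efficiency, the
age-appropriate threshold (85%, or 80% from age 65), and the weekly
sleep-needs report:

* SE at or above threshold **and** low unmet sleep need: extend TIB by one
  15-minute step. A high unmet need blocks the extension (the participant
  is already not sleeping enough by their own report) but never forces a
  restriction, which depends on efficiency alone.
* SE below threshold minus a 5-point hold band: restrict by one step.
* Anything between: hold.

Two quantities are design choices the protocol leaves open. The 5-point
hold band prevents week-to-week oscillation around the target, mirroring
common CBT-I titration practice. The TIB bounds of 300–600 minutes encode
the standard 5-hour sleep-restriction safety floor and a ceiling beyond
which restriction is meaningless; all recommendations are clamped there
and stay on the 15-minute grid. The first restriction week (week 2;
week 1 is sleep-hygiene education) starts from the prior week's average
sleep time rounded *up* to the grid — restricting below the sleep actually
obtained would be punitive as an opening move.

The plan itself is pure arithmetic: `bedtime = wake - TIB (mod 24 h)`.
Notification anchors derive from the plan — wake time, late morning
(default 10:30), early afternoon (default 14:00), and 3 h and 1 h before
the target bedtime, the last carrying the wind-down flag. The daytime
defaults are configurable since the protocol names the windows but not
clock times.

## Instruments and tailoring

The Insomnia Severity Index is 7 items scored 0–4 (total 0–28) with the
standard clinical bands: 0–7 none, 8–14 mild, 15–21 moderate, 22–28
severe. The DBAS-16 response scale is configurable with a 0–10 default —
the standard instrument's format, and consistent with totals in the
40–50 range when scored as an item sum; totals are reported as sums, not
item means, and belief prioritization operates on items (the program
pairs each belief with alternative thoughts at item granularity), with
ties broken by ascending item index so the selection is deterministic.
Subscale membership is retained as metadata. The 4-item sleep-needs
assessment (0–4 per item) maps to a low/high unmet-need level by
comparing the item mean to a cutoff of 1.5, with the boundary counted as
high — a conservative choice that withholds TIB extensions in the
ambiguous case. No instrument imputes missing items; incomplete responses
are validation errors.

Motivational-interviewing tailoring maps motivation and confidence (each
0–10) independently onto three levels with cutpoints 0–3 / 4–7 / 8–10;
three levels and these cutpoints are declared defaults, configurable,
since the protocol implies but never enumerates them. The engine returns
content-catalog keys, never prose. Program components unlock cumulatively
on the weekly schedule (relaxation at week 4, dysfunctional beliefs at
week 5, maintenance at 6, review at 7).

## Feasibility statistics

Every reported percentage uses round-half-up to whole percent (29/30 →
97%), the convention that reproduces printed trial tables; attrition is
reported to 0.1%. The overall adherence rate is the mean of the seven
*unrounded* weekly rates, rounded last. Change scores are
baseline-minus-follow-up for decrease-coded outcomes, and Cohen's *d* is
computed under both common standardizations — pooled SD of the two
timepoints, and SD of the paired change scores — because the two can
differ substantially in paired designs and summary statistics alone only
support the pooled variant; neither is privileged, and with summary-only
input the change-score variant is flagged unavailable rather than
approximated. Medication use at two timepoints is compared by Pearson χ²
without continuity correction by default (the analysis-plan convention for
this design), with McNemar's test available when discordant pair counts
exist, since the data are paired.

## The synthetic cohort

`sim_params()` declares the study conditions: 30 participants over
7 weeks, baseline ISI from a normal with mean 18.5 and SD 4.6 truncated
to 9–26, engagement probability 0.98 per day, baseline prescription and
over-the-counter sleep-medication use of 23% and 47%, and baseline DBAS
totals of mean 47 (SD 10.8) correlated 0.574 with baseline ISI. The
truncated-normal sampler calibrates its latent location (by solving the
analytic truncated-mean equation) so the *truncated* distribution hits
the requested mean — plain truncation to the asymmetric 9–26 range would
shift the realized mean about 0.3 points low.

Each participant carries three latents: a nightly sleep need (normal,
mean 400 SD 40 minutes), a hyperarousal level (mean 1, SD 0.25) that
scales sleep-onset latency, WASO and terminal wakefulness, and habitual
bed habits leaving roughly 100 excess minutes in bed — together producing
baseline sleep efficiencies near 76%, typical of insomnia presentations.
A night caps sleep at the need; surplus time in bed is spent awake. Under
an active plan, nightly TIB tracks the recommendation with ±15-minute
adherence noise.

The response model is deliberately simple: each week spent under active
restriction (recommended TIB within 60 minutes of the latent need)
multiplies arousal by `1 - response_rate`. Week-7 ISI is regenerated from
the baseline score through a declared monotone link:

```
ISI7 = clamp(round(ISI0 - 0.4 * se_gain - 4.5 * (arousal0 - arousal7)
             + noise), 0, 28)
```

where `se_gain` is the *arousal-attributable* sleep-efficiency gain: the
observed week-7 SE minus the SE expected at the realized week-7 TIB had
arousal stayed at baseline. Using the raw week-7-minus-week-1 SE change
here would credit the mechanical SE shift that restriction produces even
with no physiological response; the counterfactual form keeps the link
monotone in observed SE while making `response_rate = 0` an exact null in
expectation. `response_rate = 0.24` is calibrated so the simulated mean
ISI improvement is ≈ 8 points under the default conditions (measured
8.2 over 20 seeded cohorts; 0.0 at a zero response rate). Week-7 DBAS
follows the ISI change at the ratio of the two scales' typical changes,
and improvers (week-7 ISI below 15) discontinue prescription and OTC
medication with probability 0.85 and 0.40.

Engagement is i.i.d. Bernoulli per day with diaries only on engaged days;
weekly correlation in engagement is a noted extension, not modeled.
Instrument item vectors are generated sum-exact from the intended totals,
so scoring the generated tables recovers the configured distributions
exactly.

### What the simulator does and does not show

Passing tests against this generator demonstrate that the pipeline —
diary validation, aggregation, titration, scoring, evaluation, round-trip
I/O — is internally correct and that the closed loop behaves as designed:
over 200 seeded default cohorts, mean and median sleep efficiency at
week 7 exceed week 1 and the cohort median reaches the threshold band in
well over 95% of runs. They do not validate the clinical model: real
diaries have correlated missingness, daytime napping, reporting bias and
dropout patterns the generator does not emulate, and the arousal-decay
response model is a declared construction, not an estimated mechanism.

## Numerical choices and degenerate inputs

Half-up rounding everywhere a percentage is printed; ties in belief
ranking broken by item index; a week with no diaries is an
insufficient-data result, not an error, and passes the prior TIB through
titration unchanged; zero time in bed, negative computed sleep, or a
zero-variance vector in a correlation are classed validation errors.
Dataset CSVs are written with fixed column order and row sort so the same
dataset is byte-identical on rewrite, with MD5 digests in the manifest.

## Problem sizes

The test suite runs the distributional checks at n = 10,000 (generator
calibration), 200 seeded cohorts of 30 for the closed-loop Monte-Carlo
property, and 20 cohorts for the null-response check; the whole suite
completes in a few minutes on one CPU, and `scripts/acceptance.R`
(one default cohort plus the full evaluation) in a few seconds.

## Known limitations

No actigraphy or polysomnography ingestion, nap tracking, or time-zone
handling; attrition is a Bernoulli completion flag, not a dropout process;
the simulator has no circadian-phase or two-process physiology; and the
evaluation module computes no confidence intervals for effect sizes and
applies no multiple-testing correction, matching the descriptive analysis
style of a feasibility design.
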