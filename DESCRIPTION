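Package: dcbti
Title: Sleep-Restriction Titration and Feasibility Analytics for Digital CBT-I
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational engine for app-delivered cognitive behavioral
    therapy for insomnia (CBT-I). Parses and validates Consensus-Sleep-Diary
    style nightly records, computes per-night and weekly sleep statistics
    (time in bed, total sleep time, sleep efficiency, schedule consistency),
    and runs the weekly sleep-restriction titration that adjusts recommended
    time in bed in 15-minute steps toward a sleep-efficiency target (85%, or
    80% at age 65 and over), anchoring the target bedtime to the user's
    chosen wake time and deriving the just-in-time notification schedule.
    Scores the Insomnia Severity Index with clinical bands, the DBAS-16 with
    top-belief prioritization, a brief sleep-needs assessment, and a
    screening-eligibility rule set; provides deterministic
    motivational-interviewing tailoring levels and reminder-pool assembly.
    A feasibility evaluator computes adherence, attrition, acceptability,
    change scores with Cohen's d variants, clinical-band tables, paired
    medication-use comparisons and correlations, and a seeded cohort
    simulator exercises the full seven-week closed loop (diary -> metrics ->
    plan -> next week's diary) without any participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
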