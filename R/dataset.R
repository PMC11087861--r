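dataset_schema_version <- "1.0"

dataset_tables <- c("participants", "diaries", "isi", "dbas", "sleep_needs",
                    "engagement", "medications", "acceptability", "plans")

empty_diaries <- function() data.frame(
  participant_id = character(0), date = character(0), bedtime = character(0),
  try_to_sleep_time = character(0), sol_min = integer(0),
  awakenings = integer(0), waso_min = integer(0),
  final_wake_time = character(0), out_of_bed_time = character(0),
  stringsAsFactors = FALSE)

empty_instrument <- function(n_items) {
  df <- data.frame(participant_id = character(0), timepoint = character(0),
                   stringsAsFactors = FALSE)
  for (j in seq_len(n_items)) df[[paste0("item", j)]] <- integer(0)
  df
}

empty_sleep_needs <- function() {
  df <- data.frame(participant_id = character(0), week = integer(0),
                   stringsAsFactors = FALSE)
  for (j in 1:4) df[[paste0("item", j)]] <- integer(0)
  df
}

empty_engagement <- function() data.frame(
  participant_id = character(0), date = character(0),
  stringsAsFactors = FALSE)

empty_medications <- function() data.frame(
  participant_id = character(0), timepoint = character(0),
  prescription = logical(0), otc = logical(0), stringsAsFactors = FALSE)

empty_acceptability <- function() {
  df <- data.frame(participant_id = character(0), stringsAsFactors = FALSE)
  for (j in 1:10) df[[paste0("feature", j)]] <- integer(0)
  df$satisfaction <- integer(0)
  df$recommend <- integer(0)
  df
}

empty_plans <- function() data.frame(
  participant_id = character(0), week = integer(0),
  target_wake_time = character(0), recommended_tib_min = integer(0),
  target_bedtime = character(0), branch = character(0),
  stringsAsFactors = FALSE)

empty_participants <- function() data.frame(
  participant_id = character(0), age = integer(0),
  enrollment_date = character(0), completed = logical(0),
  stringsAsFactors = FALSE)

#' Cohort dataset container
#'
#' Bundles every data stream of a 7-week cohort — participants, nightly
#' diaries, instrument responses (ISI, DBAS-16, sleep needs), engagement
#' log, medication flags, acceptability ratings and weekly plans — with a
#' provenance block (schema version, seed). Construction validates
#' referential integrity (every row's `participant_id` must exist in the
#' participants table) and that each instrument has at most one row per
#' participant per timepoint.
#'
#' @param participants,diaries,isi,dbas,sleep_needs,engagement,medications,
#'   acceptability,plans Data frames (NULL for an empty table).
#' @param provenance Named list; `schema_version` and `seed` are filled in
#'   when absent.
#' @return A `cohort_dataset` object.
#' @export
cohort_dataset <- function(participants = empty_participants(),
                           diaries = NULL, isi = NULL, dbas = NULL,
                           sleep_needs = NULL, engagement = NULL,
                           medications = NULL, acceptability = NULL,
                           plans = NULL, provenance = list()) {
  ds <- structure(
    list(participants = participants,
         diaries = diaries %||% empty_diaries(),
         isi = isi %||% empty_instrument(7L),
         dbas = dbas %||% empty_instrument(16L),
         sleep_needs = sleep_needs %||% empty_sleep_needs(),
         engagement = engagement %||% empty_engagement(),
         medications = medications %||% empty_medications(),
         acceptability = acceptability %||% empty_acceptability(),
         plans = plans %||% empty_plans(),
         provenance = utils::modifyList(
           list(schema_version = dataset_schema_version, seed = NA),
           provenance)),
    class = "cohort_dataset"
  )
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  ids <- ds$participants$participant_id
  if (anyDuplicated(ids)) {
    dcbti_error("duplicate participant_id in participants table",
                "dcbti_integrity_error")
  }
  for (tbl in setdiff(dataset_tables, "participants")) {
    unknown <- !ds[[tbl]]$participant_id %in% ids
    if (any(unknown)) {
      dcbti_error(sprintf(
        "%s row %d references unknown participant '%s'",
        tbl, which(unknown)[1],
        ds[[tbl]]$participant_id[which(unknown)[1]]),
        "dcbti_integrity_error")
    }
  }
  for (tbl in c("isi", "dbas", "medications")) {
    key <- paste(ds[[tbl]]$participant_id, ds[[tbl]]$timepoint)
    if (anyDuplicated(key)) {
      dcbti_error(sprintf(
        "%s table has more than one row per participant-timepoint", tbl),
        "dcbti_integrity_error")
    }
    bad_tp <- !ds[[tbl]]$timepoint %in% c("baseline", "week7")
    if (any(bad_tp)) {
      dcbti_error(sprintf("%s row %d has unknown timepoint '%s'",
                          tbl, which(bad_tp)[1],
                          ds[[tbl]]$timepoint[which(bad_tp)[1]]),
                  "dcbti_integrity_error")
    }
  }
  invisible(ds)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d participant(s), schema %s, seed %s\n",
              nrow(x$participants), x$provenance$schema_version,
              x$provenance$seed))
  for (tbl in setdiff(dataset_tables, "participants")) {
    cat(sprintf("  %-13s %d row(s)\n", tbl, nrow(x[[tbl]])))
  }
  invisible(x)
}

#' @export
summary.cohort_dataset <- function(object, ...) {
  print(object)
  if (nrow(object$diaries)) {
    entries <- diary_entries_from_table(object$diaries)
    se <- vapply(entries, function(e)
      derive_entry_metrics(e)$sleep_efficiency_pct, numeric(1))
    cat(sprintf("  nightly SE: median %.1f%% (IQR %.1f-%.1f)\n",
                stats::median(se), stats::quantile(se, 0.25),
                stats::quantile(se, 0.75)))
  }
  invisible(object)
}

diary_entries_from_table <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    diary_entry(df$participant_id[i], df$date[i], df$bedtime[i],
                df$try_to_sleep_time[i], df$sol_min[i], df$awakenings[i],
                df$waso_min[i], df$final_wake_time[i],
                df$out_of_bed_time[i])
  })
}

table_sort_keys <- list(
  participants = c("participant_id"),
  diaries = c("participant_id", "date"),
  isi = c("participant_id", "timepoint"),
  dbas = c("participant_id", "timepoint"),
  sleep_needs = c("participant_id", "week"),
  engagement = c("participant_id", "date"),
  medications = c("participant_id", "timepoint"),
  acceptability = c("participant_id"),
  plans = c("participant_id", "week")
)

sort_table <- function(df, keys) {
  if (!nrow(df)) return(df)
  df <- df[do.call(order, df[keys]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a cohort dataset to a directory of CSVs
#'
#' One CSV per table plus a `manifest.json` recording the schema version,
#' per-table MD5 digests and a combined content digest. Column order and
#' row sort are fixed, so the same dataset always writes byte-identical
#' files and the digest changes iff any cell changes.
#'
#' @param ds A [cohort_dataset()].
#' @param path Directory to create/write into.
#' @return The manifest (invisibly).
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  digests <- character(0)
  for (tbl in dataset_tables) {
    f <- file.path(path, paste0(tbl, ".csv"))
    df <- sort_table(ds[[tbl]], table_sort_keys[[tbl]])
    utils::write.csv(df, f, row.names = FALSE, quote = TRUE, eol = "\n")
    files[tbl] <- paste0(tbl, ".csv")
    digests[tbl] <- unname(tools::md5sum(f))
  }
  combined <- tempfile()
  writeLines(paste(names(digests), digests, sep = "  "), combined)
  manifest <- list(
    schema_version = ds$provenance$schema_version,
    seed = ds$provenance$seed,
    generator = ds$provenance$generator %||% NA,
    tables = as.list(files),
    table_md5 = as.list(digests),
    content_digest = unname(tools::md5sum(combined))
  )
  unlink(combined)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort dataset from a directory of CSVs
#'
#' Requires the `manifest.json` written by [write_dataset()]; the schema
#' version must match and all dataset-level invariants are re-checked on
#' load.
#'
#' @param path Directory containing the CSVs and manifest.
#' @param schema_version Expected schema version.
#' @return A [cohort_dataset()].
#' @export
read_dataset <- function(path, schema_version = dataset_schema_version) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    dcbti_error(sprintf("no manifest.json in '%s': not a cohort dataset",
                        path), "dcbti_manifest_absent")
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$schema_version, schema_version)) {
    dcbti_error(sprintf("schema version mismatch: file has %s, expected %s",
                        manifest$schema_version, schema_version),
                "dcbti_schema_error")
  }
  tabs <- lapply(dataset_tables, function(tbl) {
    f <- file.path(path, paste0(tbl, ".csv"))
    if (!file.exists(f)) {
      dcbti_error(sprintf("table file missing: %s.csv", tbl),
                  "dcbti_schema_error")
    }
    proto <- switch(tbl,
                    participants = empty_participants(),
                    diaries = empty_diaries(),
                    isi = empty_instrument(7L),
                    dbas = empty_instrument(16L),
                    sleep_needs = empty_sleep_needs(),
                    engagement = empty_engagement(),
                    medications = empty_medications(),
                    acceptability = empty_acceptability(),
                    plans = empty_plans())
    df <- utils::read.csv(f, stringsAsFactors = FALSE,
                          colClasses = vapply(proto, function(col)
                            class(col)[1], character(1)))
    df
  })
  names(tabs) <- dataset_tables
  cohort_dataset(
    participants = tabs$participants, diaries = tabs$diaries,
    isi = tabs$isi, dbas = tabs$dbas, sleep_needs = tabs$sleep_needs,
    engagement = tabs$engagement, medications = tabs$medications,
    acceptability = tabs$acceptability, plans = tabs$plans,
    provenance = list(schema_version = manifest$schema_version,
                      seed = manifest$seed,
                      generator = manifest$generator)
  )
}
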