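# Reading, validating and period-partitioning EHR action logs and patient
# tables, and reducing action events to patient-day units.

#' Action categories recognised in an audit log
#'
#' The six classes of EHR actions a clinician can commit to a patient record:
#' documenting conditions, procedures, medications, notes, orders and
#' measurements.
#'
#' @export
action_categories <- function() {
  c("condition", "procedure", "medication", "note", "order", "measurement")
}

event_columns <- function() {
  c("clinician_id", "specialty", "patient_id", "timestamp", "action_category")
}

patient_columns <- function() {
  c("patient_id", "admit_date", "discharge_date", "sex", "race", "ethnicity",
    "age_days", "disposition", "excluded")
}

sex_levels <- function() c("female", "male", "unknown")
race_levels <- function() c("white", "african_american", "asian", "other")
ethnicity_levels <- function() c("non_hispanic", "latino", "unknown")
disposition_levels <- function() {
  c("home", "expired", "hospice", "short_term_hospital", "other")
}

#' Read an EHR action-event log
#'
#' Parses a delimited event log (CSV with header) into a validated event
#' table. Each row is one clinician action on one patient's record at one
#' timestamp. Rows that cannot be parsed (bad timestamp, unknown action
#' category, empty identifiers) are rejected individually with a
#' line-numbered report rather than failing the whole file; a missing
#' required column is a hard error.
#'
#' Timestamps are ISO-8601; a bare date is accepted (day resolution is all
#' the pipeline needs). The calendar day used for tie construction is the
#' date of the timestamp in `timezone`.
#'
#' @param path path to a CSV file with columns
#'   `clinician_id,specialty,patient_id,timestamp,action_category`.
#' @param timezone IANA timezone in which calendar days are binned.
#' @return A data frame of events sorted by (day, clinician_id, patient_id)
#'   with a `day` Date column, carrying a `rejects` attribute: a data frame
#'   with columns `line` (1-based file line) and `reason`.
#' @export
read_events <- function(path, timezone = "UTC") {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  missing <- setdiff(event_columns(), names(raw))
  if (length(missing) > 0L) {
    stop("event file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  raw <- raw[event_columns()]
  validate_events(raw, timezone = timezone, source = path)
}

# Shared validation for events arriving from file or from the generator.
validate_events <- function(raw, timezone = "UTC", source = "<events>") {
  n <- nrow(raw)
  reason <- character(n)
  ts <- parse_timestamp(raw$timestamp, timezone)
  reason[is.na(ts$day)] <- "unparseable timestamp"
  bad_cat <- !(raw$action_category %in% action_categories())
  reason[bad_cat & !nzchar(reason)] <- "unknown category"
  bad_id <- !nzchar(raw$clinician_id) | !nzchar(raw$patient_id)
  reason[bad_id & !nzchar(reason)] <- "empty identifier"

  keep <- !nzchar(reason)
  rejects <- data.frame(line = which(!keep) + 1L,  # +1 for the header row
                        reason = reason[!keep], stringsAsFactors = FALSE)
  ev <- raw[keep, , drop = FALSE]
  ev$timestamp <- ts$canonical[keep]
  ev$day <- ts$day[keep]

  # One clinician id maps to exactly one specialty within one dataset.
  sp <- unique(ev[c("clinician_id", "specialty")])
  dup <- sp$clinician_id[duplicated(sp$clinician_id)]
  if (length(dup) > 0L) {
    stop("clinician id(s) mapped to more than one specialty in ", source,
         ": ", paste(unique(dup), collapse = ", "))
  }

  ord <- order(ev$day, ev$clinician_id, ev$patient_id, method = "radix")
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "rejects") <- rejects
  attr(ev, "timezone") <- timezone
  ev
}

# ISO-8601 parse; returns the calendar day and a canonical rendering.
parse_timestamp <- function(x, timezone) {
  x <- gsub("T", " ", trimws(x), fixed = TRUE)
  has_time <- grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}", x)
  date_only <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  ts <- rep(as.POSIXct(NA), length(x))
  ts[has_time] <- as.POSIXct(x[has_time], tz = timezone,
                             tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
  ts[date_only] <- as.POSIXct(x[date_only], tz = timezone, format = "%Y-%m-%d")
  day <- as.Date(ts, tz = timezone)
  # Reject impossible dates that strptime silently rolls over or drops.
  canonical <- ifelse(has_time, format(ts, "%Y-%m-%d %H:%M:%S", tz = timezone),
                      format(day, "%Y-%m-%d"))
  list(day = day, canonical = canonical)
}

#' Write events in canonical CSV form
#'
#' Canonical form: the five standard columns in fixed order, rows sorted by
#' (day, clinician_id, patient_id), timestamps rendered as ISO-8601.
#' `write_events(read_events(f))` is idempotent: re-reading and re-writing
#' the output reproduces it byte for byte.
#'
#' @param events event table from [read_events()] or [generate_events()].
#' @param path output path.
#' @export
write_events <- function(events, path) {
  out <- events[event_columns()]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a patient table
#'
#' One row per NICU admission: identifiers, admission and discharge dates,
#' demographics, age at admission in days, discharge disposition and an
#' exclusion flag (e.g. COVID-19 positivity). Rows violating the schema
#' (discharge before admission, unknown category levels, negative age) are
#' rejected with a line-numbered report.
#'
#' @param path CSV with columns
#'   `patient_id,admit_date,discharge_date,sex,race,ethnicity,age_days,disposition,excluded`.
#' @return Data frame with Date columns, integer `age_days`, logical
#'   `excluded`, a derived `los_days` column (discharge minus admission),
#'   and a `rejects` attribute.
#' @export
read_patients <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  missing <- setdiff(patient_columns(), names(raw))
  if (length(missing) > 0L) {
    stop("patient file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(raw)
  admit <- as.Date(raw$admit_date, format = "%Y-%m-%d")
  disch <- as.Date(raw$discharge_date, format = "%Y-%m-%d")
  age <- suppressWarnings(as.integer(raw$age_days))
  reason <- character(n)
  reason[is.na(admit) | is.na(disch)] <- "unparseable date"
  reason[!nzchar(reason) & disch < admit] <- "discharge before admission"
  reason[!nzchar(reason) & !(raw$sex %in% sex_levels())] <- "unknown sex"
  reason[!nzchar(reason) & !(raw$race %in% race_levels())] <- "unknown race"
  reason[!nzchar(reason) & !(raw$ethnicity %in% ethnicity_levels())] <- "unknown ethnicity"
  reason[!nzchar(reason) & !(raw$disposition %in% disposition_levels())] <- "unknown disposition"
  reason[!nzchar(reason) & (is.na(age) | age < 0L)] <- "invalid age"

  keep <- !nzchar(reason)
  rejects <- data.frame(line = which(!keep) + 1L, reason = reason[!keep],
                        stringsAsFactors = FALSE)
  pt <- raw[keep, , drop = FALSE]
  pt$admit_date <- admit[keep]
  pt$discharge_date <- disch[keep]
  pt$age_days <- age[keep]
  pt$excluded <- pt$excluded %in% c("TRUE", "True", "true", "1", "yes")
  pt$los_days <- as.integer(pt$discharge_date - pt$admit_date)
  rownames(pt) <- NULL
  attr(pt, "rejects") <- rejects
  pt
}

#' Write a patient table
#' @param patients patient table as returned by [read_patients()] or
#'   [generate_patients()].
#' @param path output path.
#' @export
write_patients <- function(patients, path) {
  out <- patients[patient_columns()]
  out$admit_date <- format(out$admit_date, "%Y-%m-%d")
  out$discharge_date <- format(out$discharge_date, "%Y-%m-%d")
  out$excluded <- ifelse(out$excluded, "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Define a study period
#'
#' @param label period label, e.g. `"pre"` or `"intra"`.
#' @param start,end first and last calendar day of the window (inclusive).
#' @return A `study_period` list.
#' @export
study_period <- function(label, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("unparseable period dates for ", label)
  if (start > end) stop("period ", label, ": start date after end date")
  structure(list(label = label, start = start, end = end),
            class = "study_period")
}

#' The default pre/intra study windows
#'
#' Pre-pandemic: September-December 2019. Intra-pandemic: March-June 2020.
#' Periods are configuration, not constants, so the pipeline generalises to
#' other care-disruption studies.
#'
#' @return List of two [study_period()] objects named `pre` and `intra`.
#' @export
default_periods <- function() {
  list(pre = study_period("pre", "2019-09-01", "2019-12-31"),
       intra = study_period("intra", "2020-03-01", "2020-06-30"))
}

check_periods <- function(periods) {
  stopifnot(length(periods) >= 1L)
  for (p in periods) {
    if (!inherits(p, "study_period")) stop("periods must be study_period objects")
  }
  if (length(periods) > 1L) {
    for (i in seq_len(length(periods) - 1L)) for (j in seq(i + 1L, length(periods))) {
      a <- periods[[i]]; b <- periods[[j]]
      if (a$start <= b$end && b$start <= a$end) {
        stop("study periods overlap: ", a$label, " (", a$start, "..", a$end,
             ") and ", b$label, " (", b$start, "..", b$end, ")")
      }
    }
  }
  invisible(periods)
}

#' Partition events into study periods
#'
#' An event belongs to a period iff its calendar day lies in the period's
#' inclusive window. Events falling in no window (e.g. the January-February
#' 2020 gap between the default windows) are dropped and counted.
#'
#' @param events event table with a `day` column.
#' @param periods list of non-overlapping [study_period()] objects
#'   (default: [default_periods()]).
#' @return Named list of event tables, one per period label, with a
#'   `dropped` attribute giving the number of out-of-window events.
#' @export
partition_by_period <- function(events, periods = default_periods()) {
  check_periods(periods)
  assigned <- rep(NA_character_, nrow(events))
  for (p in periods) {
    assigned[events$day >= p$start & events$day <= p$end] <- p$label
  }
  out <- lapply(periods, function(p) {
    e <- events[!is.na(assigned) & assigned == p$label, , drop = FALSE]
    rownames(e) <- NULL
    e
  })
  names(out) <- vapply(periods, `[[`, character(1), "label")
  attr(out, "dropped") <- sum(is.na(assigned))
  out
}

#' Reduce events to patient-day units
#'
#' A patient day is one patient on one calendar day; the reduction keeps one
#' unit per distinct (clinician, patient, day) triple, however many actions
#' the clinician committed that day. This is the unit in which tie weights
#' are counted. The reduction is a set operation: idempotent and invariant
#' to event order.
#'
#' @param events event table with `day`.
#' @return Data frame with columns `clinician_id`, `patient_id`, `day`,
#'   one row per distinct triple, sorted.
#' @export
to_patient_days <- function(events) {
  pd <- unique(events[c("clinician_id", "patient_id", "day")])
  ord <- order(pd$day, pd$clinician_id, pd$patient_id, method = "radix")
  pd <- pd[ord, , drop = FALSE]
  rownames(pd) <- NULL
  pd
}

#' Remove events of excluded patients
#'
#' Drops all events for patients whose `excluded` flag is set in the patient
#' table (the study's COVID-19-positive exclusion is a flag of this kind).
#' Events referencing a patient absent from the table are kept with a
#' warning by default, because audit logs routinely outlive patient-table
#' extracts.
#'
#' @param events event table.
#' @param patients patient table with `patient_id` and logical `excluded`.
#' @param on_missing `"warn"` (keep the events, warn) or `"error"`.
#' @return Filtered event table with attribute `n_excluded_patients`.
#' @export
filter_patients <- function(events, patients, on_missing = c("warn", "error")) {
  on_missing <- match.arg(on_missing)
  unknown <- setdiff(unique(events$patient_id), patients$patient_id)
  if (length(unknown) > 0L) {
    msg <- paste0(length(unknown), " patient id(s) in events absent from patient table")
    if (on_missing == "error") stop(msg) else warning(msg)
  }
  flagged <- patients$patient_id[patients$excluded]
  out <- events[!(events$patient_id %in% flagged), , drop = FALSE]
  if (nrow(out) == 0L && nrow(events) > 0L) {
    warning("all events removed by patient exclusion")
  }
  rownames(out) <- NULL
  attr(out, "n_excluded_patients") <- sum(patients$excluded)
  attr(out, "rejects") <- attr(events, "rejects")
  out
}
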