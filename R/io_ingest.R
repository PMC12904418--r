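# Readers for the raw study inputs: watch-export XML (sleep stages, step
# counts) and the hand-coded screen-time table, plus the tidy panel
# interchange format and pseudonymization.

SLEEP_TYPE <- "HKCategoryTypeIdentifierSleepAnalysis"
STEP_TYPE  <- "HKQuantityTypeIdentifierStepCount"

# watch export vocabulary varies by OS version; stage-resolved values and the
# legacy unresolved ones are both accepted. "Asleep"/"AsleepUnspecified" map
# to core (N1/N2 is the closest stage); "InBed" is not a sleep stage and is
# counted separately.
STAGE_MAP <- c(
  "HKCategoryValueSleepAnalysisAwake"             = "awake",
  "HKCategoryValueSleepAnalysisAsleepREM"         = "rem",
  "HKCategoryValueSleepAnalysisAsleepCore"        = "core",
  "HKCategoryValueSleepAnalysisAsleepDeep"        = "deep",
  "HKCategoryValueSleepAnalysisAsleep"            = "core",
  "HKCategoryValueSleepAnalysisAsleepUnspecified" = "core"
)
INBED_VALUE <- "HKCategoryValueSleepAnalysisInBed"

read_hk_xml <- function(stream) {
  tryCatch(
    xml2::read_xml(stream),
    error = function(e) {
      msg <- conditionMessage(e)
      ln <- suppressWarnings(as.integer(sub(".*line[ :]+([0-9]+).*", "\\1", msg)))
      off <- NA_integer_
      if (!is.na(ln) && is.character(stream) && !file.exists(stream)) {
        lines <- strsplit(stream, "\n", fixed = TRUE)[[1]]
        off <- if (ln <= length(lines)) sum(nchar(lines[seq_len(ln - 1)], type = "bytes")) + (ln - 1L) else NA_integer_
      } else if (!is.na(ln) && is.character(stream) && file.exists(stream)) {
        lines <- readLines(stream, n = ln, warn = FALSE)
        off <- sum(nchar(lines[seq_len(min(ln - 1, length(lines)))], type = "bytes")) + (ln - 1L)
      }
      stop(sprintf("malformed XML (line %s, byte offset %s): %s",
                   ifelse(is.na(ln), "?", ln), ifelse(is.na(off), "?", off), msg),
           call. = FALSE)
    }
  )
}

hk_records <- function(doc) xml2::xml_find_all(doc, ".//Record")

apply_window <- function(start, window) {
  if (is.null(window)) rep(TRUE, length(start))
  else start >= window[1] & start < window[2]   # [start, end)
}

#' Read sleep-stage records from a watch-export XML stream
#'
#' Keeps only sleep-analysis `Record` elements, maps export stage strings onto
#' `awake`/`rem`/`core`/`deep`, converts timestamps into the study timezone and
#' drops records starting outside the configured study window. Awake episodes
#' are retained (they are excluded later from sleep sums). Unknown stage
#' strings are skipped and counted.
#'
#' @param stream path to an XML file or a single XML string.
#' @param participant_id raw participant identifier for this export.
#' @param id_map optional named character vector mapping raw ids to pseudonyms.
#' @param study_window optional POSIXct length-2 vector; records with
#'   `start` outside `[study_window[1], study_window[2])` are dropped.
#' @param tz study timezone for all returned timestamps.
#' @return data.frame with columns `participant_id`, `stage`, `start`, `end`;
#'   attribute `"warnings"` is a named list of skip counters.
#' @export
read_sleep_xml <- function(stream, participant_id = "unknown", id_map = NULL,
                           study_window = NULL, tz = "Europe/Brussels") {
  doc <- read_hk_xml(stream)
  recs <- hk_records(doc)
  type <- xml2::xml_attr(recs, "type")
  keep <- !is.na(type) & type == SLEEP_TYPE
  recs <- recs[keep]
  warn <- list(unknown_stage = 0L, inbed_skipped = 0L, non_sleep_records = sum(!keep))
  if (length(recs) == 0L) {
    out <- data.frame(participant_id = character(), stage = character(),
                      start = as.POSIXct(character(), tz = tz),
                      end = as.POSIXct(character(), tz = tz))
    attr(out, "warnings") <- warn
    return(out)
  }
  value <- xml2::xml_attr(recs, "value")
  stage <- unname(STAGE_MAP[value])
  inbed <- !is.na(value) & value == INBED_VALUE
  unknown <- is.na(stage) & !inbed
  warn$inbed_skipped <- sum(inbed)
  warn$unknown_stage <- sum(unknown)
  if (warn$unknown_stage > 0)
    warning(sprintf("skipped %d record(s) with unknown sleep value", warn$unknown_stage))
  ok <- !is.na(stage)
  start <- parse_hk_time(xml2::xml_attr(recs, "startDate")[ok], tz)
  end <- parse_hk_time(xml2::xml_attr(recs, "endDate")[ok], tz)
  if (any(end <= start)) stop("sleep record with end <= start")
  pid <- if (!is.null(id_map)) unname(id_map[participant_id]) else participant_id
  out <- data.frame(participant_id = rep(pid, sum(ok)),
                    stage = stage[ok], start = start, end = end,
                    stringsAsFactors = FALSE)
  out <- out[apply_window(out$start, study_window), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "warnings") <- warn
  out
}

#' Read step-count records from a watch-export XML stream
#'
#' @inheritParams read_sleep_xml
#' @return data.frame with columns `participant_id`, `start`, `end`, `steps`;
#'   attribute `"warnings"` counts skipped non-step records.
#' @export
read_steps_xml <- function(stream, participant_id = "unknown", id_map = NULL,
                           study_window = NULL, tz = "Europe/Brussels") {
  doc <- read_hk_xml(stream)
  recs <- hk_records(doc)
  type <- xml2::xml_attr(recs, "type")
  keep <- !is.na(type) & type == STEP_TYPE
  warn <- list(non_step_records = sum(!keep))
  recs <- recs[keep]
  if (length(recs) == 0L) {
    out <- data.frame(participant_id = character(),
                      start = as.POSIXct(character(), tz = tz),
                      end = as.POSIXct(character(), tz = tz),
                      steps = numeric())
    attr(out, "warnings") <- warn
    return(out)
  }
  steps <- as.numeric(xml2::xml_attr(recs, "value"))
  if (anyNA(steps)) stop("step record with non-numeric count")
  if (any(steps < 0)) stop("step record with negative count")
  start <- parse_hk_time(xml2::xml_attr(recs, "startDate"), tz)
  end <- parse_hk_time(xml2::xml_attr(recs, "endDate"), tz)
  if (any(end < start)) stop("step record with end < start")
  pid <- if (!is.null(id_map)) unname(id_map[participant_id]) else participant_id
  out <- data.frame(participant_id = rep(pid, length(steps)),
                    start = start, end = end, steps = steps,
                    stringsAsFactors = FALSE)
  out <- out[apply_window(out$start, study_window), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "warnings") <- warn
  out
}

#' Read the hand-coded screen-time table
#'
#' The screen-time reports are coded into a CSV with columns
#' `participant,date,hour,seconds`, where `hour` is 0-23 for hourly usage rows
#' and the literal `"daily"` for the day's total. Hourly rows above 3600 s and
#' duplicate `(participant, date, hour)` keys are validation errors. Days whose
#' hourly sum exceeds the coded daily total by more than 5% are flagged (the
#' on-screen values are rounded, not guaranteed consistent).
#'
#' @param csv path to the coded CSV file.
#' @return list with data.frames `hourly` (`participant_id`, `date`, `hour`,
#'   `seconds_used`) and `daily` (`participant_id`, `date`, `seconds_used`);
#'   attribute `"flags"` lists inconsistent participant-days.
#' @export
read_usage_table <- function(csv) {
  df <- utils::read.csv(csv, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character", "numeric"))
  need <- c("participant", "date", "hour", "seconds")
  if (!all(need %in% names(df))) stop("usage table must have columns ", paste(need, collapse = ","))
  if (any(is.na(df$seconds)) || any(df$seconds < 0)) stop("usage seconds must be non-negative")
  key <- paste(df$participant, df$date, df$hour)
  if (anyDuplicated(key)) stop("duplicate (participant,date,hour) key in usage table: ",
                               key[duplicated(key)][1])
  is_daily <- df$hour == "daily"
  hourly <- df[!is_daily, , drop = FALSE]
  hr <- suppressWarnings(as.integer(hourly$hour))
  if (anyNA(hr) && nrow(hourly) > 0) stop("hour must be 0-23 or 'daily'")
  if (nrow(hourly) > 0 && (any(hr < 0) || any(hr > 23))) stop("hour must be 0-23 or 'daily'")
  if (any(hourly$seconds > 3600)) stop("hourly usage exceeds 3600 seconds")
  hourly_out <- data.frame(participant_id = hourly$participant,
                           date = as.Date(hourly$date), hour = hr,
                           seconds_used = hourly$seconds, stringsAsFactors = FALSE)
  daily <- df[is_daily, , drop = FALSE]
  daily_out <- data.frame(participant_id = daily$participant,
                          date = as.Date(daily$date),
                          seconds_used = daily$seconds, stringsAsFactors = FALSE)
  # consistency flags: hourly sum > 1.05 * daily total
  flags <- character()
  if (nrow(hourly_out) > 0 && nrow(daily_out) > 0) {
    hs <- stats::aggregate(seconds_used ~ participant_id + date, data = hourly_out, FUN = sum)
    mg <- merge(hs, daily_out, by = c("participant_id", "date"),
                suffixes = c("_hourly", "_daily"))
    bad <- mg$seconds_used_hourly > 1.05 * mg$seconds_used_daily
    flags <- paste(mg$participant_id[bad], mg$date[bad])
  }
  out <- list(hourly = hourly_out, daily = daily_out)
  attr(out, "flags") <- flags
  out
}

#' Replace raw participant ids with salted pseudonyms
#'
#' Deterministic for a fixed salt, different across salts, and injective in
#' practice (52-bit hash). The raw-to-pseudonym mapping is attached as an
#' attribute for the caller to store securely; the records themselves carry no
#' trace of the raw ids.
#'
#' @param records data.frame with a `participant_id` column.
#' @param salt character scalar from the run configuration.
#' @return `records` with pseudonymized ids; attribute `"id_map"` holds the
#'   raw-to-pseudonym mapping.
#' @export
pseudonymize <- function(records, salt) {
  stopifnot("participant_id" %in% names(records))
  raw <- unique(records$participant_id)
  map <- stats::setNames(hash_id(raw, salt), raw)
  records$participant_id <- unname(map[records$participant_id])
  attr(records, "id_map") <- map
  records
}

PANEL_COLS <- c("participant_id", "day_index", "date", "tsu_s", "suib_s",
                "sleep_total_s", "rem_s", "core_s", "deep_s")

#' Write / read the tidy person-day panel
#'
#' The interchange dialect is a plain CSV with one row per participant-day,
#' ISO dates, and all durations as integer seconds (missing cells empty).
#' `read_panel(write_panel(x))` reproduces `x` and a write of a read file is
#' byte-identical.
#'
#' @param panel data.frame with columns `participant_id`, `day_index`, `date`,
#'   `tsu_s`, `suib_s`, `sleep_total_s`, `rem_s`, `core_s`, `deep_s`.
#' @param path output CSV path.
#' @return `write_panel` returns `path` invisibly; `read_panel` the panel.
#' @export
write_panel <- function(panel, path) {
  stopifnot(all(PANEL_COLS %in% names(panel)))
  out <- panel[PANEL_COLS]
  out <- out[order(out$participant_id, out$day_index), , drop = FALSE]
  num <- setdiff(PANEL_COLS, c("participant_id", "date"))
  for (v in num) out[[v]] <- ifelse(is.na(out[[v]]), "", format(round(as.numeric(out[[v]])), scientific = FALSE, trim = TRUE))
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  lines <- c(paste(PANEL_COLS, collapse = ","),
             do.call(paste, c(unname(as.list(out)), sep = ",")))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character", day_index = "integer",
                                       date = "character", tsu_s = "numeric", suib_s = "numeric",
                                       sleep_total_s = "numeric", rem_s = "numeric",
                                       core_s = "numeric", deep_s = "numeric"))
  df$date <- as.Date(df$date)
  df
}

#' Write the ingest warnings sidecar
#' @param warnings named list of warning counters per input.
#' @param path output JSON path.
#' @export
write_ingest_report <- function(warnings, path) {
  jsonlite::write_json(warnings, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
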