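# Nightly in-bed interval inference from step-count accelerometry.
#
# The classifier follows common actigraphy practice: step records are rastered
# onto a regular epoch grid, each nightly search window is scanned for the
# longest sustained low-activity run, brief interior activity bursts are kept
# as wake-after-sleep-onset (WASO), and a sustained activity burst confirms a
# bed exit.

#' Detector parameters for in-bed inference
#'
#' @param epoch_minutes epoch length of the step raster (minutes).
#' @param low_step_threshold epochs with fewer steps than this count as
#'   low-activity.
#' @param window_start,window_end clock times (\code{"HH:MM"}) bounding the
#'   nightly search window; the window spans midnight (evening into next day).
#' @param min_inbed_hours minimum duration for a run to count as an in-bed
#'   interval.
#' @param max_waso_epochs longest interior activity burst still absorbed as
#'   WASO.
#' @param confirm_exit_epochs consecutive active epochs that confirm a bed
#'   exit (takes precedence over WASO absorption when both rules apply).
#' @return object of class `detector_params`.
#' @export
detector_params <- function(epoch_minutes = 10, low_step_threshold = 5,
                            window_start = "20:00", window_end = "12:00",
                            min_inbed_hours = 3, max_waso_epochs = 3,
                            confirm_exit_epochs = 3) {
  stopifnot(epoch_minutes > 0, low_step_threshold > 0, min_inbed_hours > 0,
            max_waso_epochs > 0, confirm_exit_epochs > 0)
  ws <- as.numeric(strsplit(window_start, ":")[[1]]) %*% c(60, 1)
  we <- as.numeric(strsplit(window_end, ":")[[1]]) %*% c(60, 1)
  if (we[1] >= ws[1]) stop("nightly window must span midnight (window_end before window_start)")
  structure(list(epoch_minutes = epoch_minutes,
                 low_step_threshold = low_step_threshold,
                 window_start = window_start, window_end = window_end,
                 window_start_min = as.numeric(ws), window_end_min = as.numeric(we),
                 min_inbed_hours = min_inbed_hours,
                 max_waso_epochs = max_waso_epochs,
                 confirm_exit_epochs = confirm_exit_epochs),
            class = "detector_params")
}

#' Raster step records onto a regular epoch grid
#'
#' Each record's steps are apportioned to epochs proportionally to temporal
#' overlap; overlapping records simply add. Epochs never touched by any record
#' carry `NA` (no device coverage), distinct from an observed zero.
#'
#' @param step_records data.frame from [read_steps_xml()] for one participant.
#' @param params a [detector_params()] object.
#' @return object of class `epoch_series`: list with `participant_id`,
#'   `epoch_start` (POSIXct grid), `steps` (counts, `NA` = no coverage) and
#'   `epoch_minutes`.
#' @export
epoch_steps <- function(step_records, params = detector_params()) {
  stopifnot(nrow(step_records) > 0)
  pid <- unique(step_records$participant_id)
  if (length(pid) != 1L) stop("epoch_steps expects records for a single participant")
  el <- params$epoch_minutes * 60
  t0 <- floor(as.numeric(min(step_records$start)) / el) * el
  t1 <- ceiling(as.numeric(max(step_records$end)) / el) * el
  if (t1 <= t0) t1 <- t0 + el
  starts <- seq(t0, t1 - el, by = el)
  steps <- rep(0, length(starts))
  covered <- rep(FALSE, length(starts))
  for (i in seq_len(nrow(step_records))) {
    a <- as.numeric(step_records$start[i]); b <- as.numeric(step_records$end[i])
    dur <- b - a
    i0 <- max(1L, floor((a - t0) / el) + 1L)
    i1 <- min(length(starts), floor((b - t0 - 1e-9) / el) + 1L)
    if (i1 < i0) i1 <- i0
    idx <- i0:i1
    ov <- pmin(b, starts[idx] + el) - pmax(a, starts[idx])
    ov[ov < 0] <- 0
    covered[idx] <- covered[idx] | ov > 0 | dur == 0
    if (dur <= 0) {
      steps[i0] <- steps[i0] + step_records$steps[i]
      covered[i0] <- TRUE
    } else {
      steps[idx] <- steps[idx] + step_records$steps[i] * ov / dur
    }
  }
  steps[!covered] <- NA_real_
  structure(list(participant_id = pid,
                 epoch_start = as.POSIXct(starts, origin = "1970-01-01",
                                          tz = attr(step_records$start, "tzone") %||% "UTC"),
                 steps = steps, epoch_minutes = params$epoch_minutes),
            class = "epoch_series")
}

# core run-finder on a logical activity vector; active NA means no coverage.
# Returns the selected run as c(i, j) epoch indices plus WASO burst indices,
# or NULL when no qualifying run exists.
find_inbed_run <- function(active, params) {
  n <- length(active)
  if (n == 0L || all(is.na(active))) return(NULL)
  act <- ifelse(is.na(active), FALSE, active)  # coverage gaps count as inactivity evidence
  r <- rle(act)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  # an active segment breaks a run when it confirms an exit or is too long for WASO
  breaker <- r$values & (r$lengths >= params$confirm_exit_epochs |
                           r$lengths > params$max_waso_epochs)
  # group contiguous non-breaker segments
  grp <- cumsum(breaker)
  best <- NULL
  for (g in unique(grp[!breaker])) {
    segs <- which(grp == g & !breaker)
    # trim leading/trailing active (WASO must be interior)
    while (length(segs) && r$values[segs[1]]) segs <- segs[-1]
    while (length(segs) && r$values[segs[length(segs)]]) segs <- segs[-length(segs)]
    if (!length(segs)) next
    i <- starts[segs[1]]; j <- ends[segs[length(segs)]]
    span <- j - i + 1L
    if (span * params$epoch_minutes < params$min_inbed_hours * 60) next
    if (is.null(best) || span > best$span) {
      waso_segs <- segs[r$values[segs]]
      best <- list(i = i, j = j, span = span,
                   waso = cbind(starts[waso_segs], ends[waso_segs]))
    }
  }
  best
}

#' Detect nightly in-bed intervals
#'
#' For every nightly search window covered by the epoch series, finds the
#' longest sustained low-activity run (epochs with steps below
#' `low_step_threshold`; coverage gaps count as inactivity evidence). Interior
#' activity bursts short enough for WASO are absorbed as WASO sub-intervals; a
#' burst of at least `confirm_exit_epochs` active epochs terminates the run.
#' At most one interval is returned per night (the longest; ties go to the
#' earliest). Nights whose window is entirely uncovered are flagged missing.
#'
#' @param epochs an [epoch_steps()] series.
#' @param params a [detector_params()] object.
#' @return data.frame with one row per detected night: `participant_id`,
#'   `night` (the evening's calendar date), `enter`, `exit`, `n_waso`,
#'   `waso_minutes`, and a list column `waso` of data.frames with `start`/`end`
#'   timestamps. Attribute `"missing_nights"` lists flagged dates.
#' @export
detect_inbed <- function(epochs, params = detector_params()) {
  stopifnot(inherits(epochs, "epoch_series"))
  tz <- attr(epochs$epoch_start, "tzone") %||% "UTC"
  el <- params$epoch_minutes * 60
  t_first <- epochs$epoch_start[1]
  t_last <- epochs$epoch_start[length(epochs$epoch_start)] + el
  # candidate nights: evening dates whose window overlaps the covered span
  d0 <- as.Date(t_first, tz = tz) - 1
  d1 <- as.Date(t_last, tz = tz)
  nights <- seq(d0, d1, by = "day")
  active <- epochs$steps >= params$low_step_threshold
  rows <- list(); wasos <- list(); missing_nights <- as.Date(character())
  for (night in as.list(nights)) {
    w0 <- as.POSIXct(paste(night, paste0(params$window_start, ":00")), tz = tz)
    w1 <- as.POSIXct(paste(night + 1, paste0(params$window_end, ":00")), tz = tz)
    idx <- which(epochs$epoch_start >= w0 & epochs$epoch_start < w1)
    if (!length(idx)) next
    if (all(is.na(epochs$steps[idx]))) { missing_nights <- c(missing_nights, night); next }
    run <- find_inbed_run(active[idx], params)
    if (is.null(run)) { missing_nights <- c(missing_nights, night); next }
    enter <- epochs$epoch_start[idx[run$i]]
    exit <- epochs$epoch_start[idx[run$j]] + el
    wdf <- if (nrow(run$waso)) {
      data.frame(start = epochs$epoch_start[idx[run$waso[, 1]]],
                 end = epochs$epoch_start[idx[run$waso[, 2]]] + el)
    } else data.frame(start = as.POSIXct(character(), tz = tz),
                      end = as.POSIXct(character(), tz = tz))
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = epochs$participant_id, night = night,
      enter = enter, exit = exit, n_waso = nrow(wdf),
      waso_minutes = if (nrow(wdf)) sum(as.numeric(wdf$end - wdf$start, units = "mins")) else 0,
      stringsAsFactors = FALSE)
    wasos[[length(wasos) + 1L]] <- wdf
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(), night = as.Date(character()),
               enter = as.POSIXct(character(), tz = tz),
               exit = as.POSIXct(character(), tz = tz),
               n_waso = integer(), waso_minutes = numeric())
  out$waso <- if (length(wasos)) I(wasos) else I(list())
  attr(out, "missing_nights") <- missing_nights
  out
}

#' Per-night in-bed presence flags
#'
#' @param intervals output of [detect_inbed()] (possibly several participants,
#'   row-bound).
#' @param study_days data.frame with `participant_id` and `night` (Date)
#'   listing the expected participant-nights.
#' @return `study_days` with a logical `present` column.
#' @export
inbed_coverage <- function(intervals, study_days) {
  stopifnot(all(c("participant_id", "night") %in% names(study_days)))
  key <- paste(intervals$participant_id, intervals$night)
  study_days$present <- paste(study_days$participant_id, study_days$night) %in% key
  study_days
}

#' Write detected intervals as a BED-like TSV plus a WASO JSON sidecar
#' @param intervals output of [detect_inbed()].
#' @param tsv,json output paths (either may be `NULL` to skip).
#' @export
write_inbed <- function(intervals, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    flat <- intervals[c("participant_id", "night", "enter", "exit", "n_waso", "waso_minutes")]
    flat$enter <- format(flat$enter, "%Y-%m-%d %H:%M:%S %z")
    flat$exit <- format(flat$exit, "%Y-%m-%d %H:%M:%S %z")
    utils::write.table(flat, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    detail <- lapply(seq_len(nrow(intervals)), function(i) {
      w <- intervals$waso[[i]]
      list(participant_id = intervals$participant_id[i],
           night = as.character(intervals$night[i]),
           enter = format(intervals$enter[i], "%Y-%m-%d %H:%M:%S %z"),
           exit = format(intervals$exit[i], "%Y-%m-%d %H:%M:%S %z"),
           waso = if (nrow(w)) data.frame(start = format(w$start, "%Y-%m-%d %H:%M:%S %z"),
                                          end = format(w$end, "%Y-%m-%d %H:%M:%S %z"))
                  else list())
    })
    jsonlite::write_json(detail, json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(intervals)
}
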