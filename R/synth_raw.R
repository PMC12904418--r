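# Raw-stream emission: given a person-day panel, produce watch-export XML
# (step counts, sleep stages) and a coded screen-time CSV that, pushed back
# through ingestion, in-bed detection and panel construction, recover the
# input panel within epoching/proration granularity.
#
# Texture is deliberately minimal (day/night activity contrast only): active
# 10-minute step epochs outside the in-bed interval, zero-step coverage
# epochs inside it, three consecutive stage blocks partitioning total sleep,
# and usage placed in whole clock hours inside (in-bed use) or away from
# (remaining use) the interval.

fmt_hk <- function(t) format(t, "%Y-%m-%d %H:%M:%S %z")

hk_record <- function(type, value, start, end) {
  sprintf('  <Record type="%s" sourceName="synthetic" value="%s" startDate="%s" endDate="%s"/>',
          type, value, fmt_hk(start), fmt_hk(end))
}

hk_doc <- function(records) {
  paste(c('<?xml version="1.0" encoding="UTF-8"?>', "<HealthData>", records, "</HealthData>"),
        collapse = "\n")
}

STAGE_VALUES <- c(core = "HKCategoryValueSleepAnalysisAsleepCore",
                  deep = "HKCategoryValueSleepAnalysisAsleepDeep",
                  rem = "HKCategoryValueSleepAnalysisAsleepREM")

#' Emit raw watch and screen-time streams reproducing a panel
#'
#' @param panel person-day panel (typically from [simulate_panel()]); days
#'   with in-bed use exceeding total use are an error.
#' @param config the [synth_config()] that produced the panel (supplies seed
#'   and start date).
#' @param params [detector_params()] the downstream detector will use; the
#'   emitted streams respect its window and minimum-duration rules.
#' @param tz study timezone.
#' @return list with `sleep_xml` and `steps_xml` (named character vectors,
#'   one XML document per participant) and `usage` (coded screen-time rows).
#' @export
simulate_raw <- function(panel, config, params = detector_params(), tz = "Europe/Brussels") {
  if (any(panel$suib_s > panel$tsu_s + 1e-6, na.rm = TRUE))
    stop("panel day with in-bed use exceeding total use")
  set.seed(derive_seed(config$seed, "raw"))
  ids <- unique(panel$participant_id)
  el <- params$epoch_minutes * 60
  sleep_xml <- steps_xml <- stats::setNames(character(length(ids)), ids)
  usage_rows <- list()
  for (pid in ids) {
    pp <- panel[panel$participant_id == pid, ]
    pp <- pp[order(pp$day_index), ]
    srecs <- character(); strecs <- character()
    intervals <- vector("list", nrow(pp))
    for (i in seq_len(nrow(pp))) {
      d <- as.Date(pp$date[i])
      sleep_s <- pp$sleep_total_s[i]
      min_s <- params$min_inbed_hours * 3600
      if (is.na(sleep_s) || sleep_s < min_s) next
      dur <- sleep_s + 1800          # 30 min of in-bed wakefulness around sleep
      w_end <- as.POSIXct(paste(d + 1, paste0(params$window_end, ":00")), tz = tz)
      w_start <- as.POSIXct(paste(d, paste0(params$window_start, ":00")), tz = tz)
      enter <- as.POSIXct(paste(d, "23:00:00"), tz = tz)
      if (enter + dur > w_end - el) enter <- w_end - el - dur
      if (enter < w_start + el) enter <- w_start + el   # extreme long sleep: truncated
      enter <- as.POSIXct(floor(as.numeric(enter) / el) * el, origin = "1970-01-01", tz = tz)
      exit <- as.POSIXct(ceiling(as.numeric(enter + dur) / el) * el, origin = "1970-01-01", tz = tz)
      exit <- min(exit, w_end)
      intervals[i] <- list(c(as.numeric(enter), as.numeric(exit)))
      # stage records: three consecutive blocks (or one legacy block when
      # stages are absent from the panel)
      s0 <- enter + 600
      if (!is.na(pp$core_s[i])) {
        for (st in c("core", "deep", "rem")) {
          len <- pp[[paste0(st, "_s")]][i]
          if (len > 0) {
            srecs <- c(srecs, hk_record(SLEEP_TYPE, STAGE_VALUES[st], s0, s0 + len))
            s0 <- s0 + len
          }
        }
      } else {
        srecs <- c(srecs, hk_record(SLEEP_TYPE, "HKCategoryValueSleepAnalysisAsleep",
                                    s0, s0 + sleep_s))
      }
    }
    # step records on the 10-min grid across the full span; active outside
    # intervals during waking hours and through un-slept nights, zero-step
    # coverage inside intervals
    span0 <- as.numeric(as.POSIXct(paste(min(pp$date), "00:00:00"), tz = tz))
    span1 <- as.numeric(as.POSIXct(paste(max(pp$date) + 1, "12:00:00"), tz = tz))
    imat <- do.call(rbind, intervals[!sapply(intervals, is.null)])
    for (t0 in seq(span0, span1 - el, by = el)) {
      inside <- !is.null(imat) && any(t0 >= imat[, 1] & t0 < imat[, 2])
      tt <- as.POSIXct(t0, origin = "1970-01-01", tz = tz)
      if (inside) {
        strecs <- c(strecs, hk_record(STEP_TYPE, 0, tt, tt + el))
      } else {
        strecs <- c(strecs, hk_record(STEP_TYPE, 40 + stats::rpois(1, 60), tt, tt + el))
      }
    }
    sleep_xml[pid] <- hk_doc(srecs)
    steps_xml[pid] <- hk_doc(strecs)
    # usage: in-bed seconds into whole hours inside the interval, remainder
    # into hours that do not touch any interval
    for (i in seq_len(nrow(pp))) {
      if (is.na(pp$tsu_s[i])) next
      d <- as.Date(pp$date[i])
      tsu <- pp$tsu_s[i]; suib <- pp$suib_s[i]
      hours_used <- numeric(0); hour_keys <- character(0)
      add_usage <- function(date, hour, secs) {
        usage_rows[[length(usage_rows) + 1L]] <<- data.frame(
          participant = pid, date = as.character(date), hour = as.character(hour),
          seconds = round(secs, 3), stringsAsFactors = FALSE)
      }
      if (!is.na(suib) && suib > 0 && !is.null(intervals[[i]])) {
        iv <- intervals[[i]]
        h0 <- ceiling(iv[1] / 3600); h1 <- floor(iv[2] / 3600)
        full_hours <- if (h1 > h0) seq(h0, h1 - 1) * 3600 else numeric(0)
        remaining <- suib
        for (hs in full_hours) {
          if (remaining <= 0) break
          put <- min(remaining, 3600)
          tt <- as.POSIXct(hs, origin = "1970-01-01", tz = tz)
          add_usage(as.Date(format(tt, "%Y-%m-%d")), as.integer(format(tt, "%H")), put)
          remaining <- remaining - put
        }
        # spill into boundary hours, scaled so the prorated recovery matches
        for (hs in c((h0 - 1) * 3600, h1 * 3600)) {
          if (remaining <= 0) break
          frac <- (min(hs + 3600, iv[2]) - max(hs, iv[1])) / 3600
          if (frac <= 0) next
          put <- min(remaining / frac, 3600)
          tt <- as.POSIXct(hs, origin = "1970-01-01", tz = tz)
          add_usage(as.Date(format(tt, "%Y-%m-%d")), as.integer(format(tt, "%H")), put)
          remaining <- remaining - put * frac
        }
      }
      # remaining (daytime) usage into afternoon/evening hours clear of all
      # intervals
      out_secs <- tsu - (if (is.na(suib)) 0 else suib)
      cand <- c(12:19, 9:11, 20:22)
      for (h in cand) {
        if (out_secs <= 0) break
        hs <- as.numeric(as.POSIXct(paste(d, sprintf("%02d:00:00", h)), tz = tz))
        if (!is.null(imat) && any(pmin(hs + 3600, imat[, 2]) - pmax(hs, imat[, 1]) > 0)) next
        put <- min(out_secs, 3600)
        add_usage(d, h, put)
        out_secs <- out_secs - put
      }
      add_usage(d, "daily", tsu)
    }
  }
  usage <- do.call(rbind, usage_rows)
  list(sleep_xml = sleep_xml, steps_xml = steps_xml, usage = usage)
}

#' Write emitted raw streams to a directory
#'
#' @param raw result of [simulate_raw()].
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_raw <- function(raw, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(sleep = character(), steps = character())
  for (pid in names(raw$sleep_xml)) {
    ps <- file.path(dir, paste0("sleep_", pid, ".xml"))
    pt <- file.path(dir, paste0("steps_", pid, ".xml"))
    writeLines(raw$sleep_xml[[pid]], ps)
    writeLines(raw$steps_xml[[pid]], pt)
    paths$sleep[pid] <- ps; paths$steps[pid] <- pt
  }
  paths$usage <- file.path(dir, "usage.csv")
  utils::write.csv(raw$usage, paths$usage, row.names = FALSE, quote = FALSE)
  paths
}
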