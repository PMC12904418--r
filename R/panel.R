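# Person-day panel construction: per-night sleep stage aggregation, total and
# in-bed smartphone use, the missingness exclusion rule, and the
# within/between (person-mean) decomposition with lag-1 copies.
#
# Night/day alignment: the total-use day d, the in-bed interval opening on
# evening d, and the sleep episode inside it all carry day index d, so
# same-day paths (total use -> in-bed use -> sleep) follow daytime -> evening
# -> night temporal order.

# map panel columns to the short variable names used by the models
VAR_COLS <- c(tsu = "tsu_s", suib = "suib_s", sleep = "sleep_total_s",
              rem = "rem_s", core = "core_s", deep = "deep_s")

night_window <- function(night, params, tz) {
  c(as.POSIXct(paste(night, paste0(params$window_start, ":00")), tz = tz),
    as.POSIXct(paste(night + 1, paste0(params$window_end, ":00")), tz = tz))
}

# union of [start, end) intervals given as a 2-column matrix of numerics
merge_intervals <- function(m) {
  if (nrow(m) <= 1) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    if (m[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else out <- rbind(out, m[i, ])
  }
  out
}

#' Aggregate sleep-stage records into per-night stage seconds
#'
#' Each record is assigned to the nightly window containing its midpoint (the
#' window opening at `window_start` on the evening's date). Overlapping
#' same-stage records are merged (union) before summation, with a warning.
#' Awake episodes are excluded from all sleep sums; total sleep is
#' rem + core + deep. A night with records but no asleep-stage seconds is
#' flagged empty.
#'
#' @param sleep_records data.frame from [read_sleep_xml()] for one participant.
#' @param params [detector_params()] supplying the nightly window bounds.
#' @return data.frame `participant_id`, `night`, `rem_s`, `core_s`, `deep_s`,
#'   `awake_s`, `sleep_total_s`; attribute `"empty_nights"`.
#' @export
aggregate_sleep <- function(sleep_records, params = detector_params()) {
  pid <- unique(sleep_records$participant_id)
  stopifnot(length(pid) <= 1L)
  tz <- attr(sleep_records$start, "tzone") %||% "UTC"
  if (nrow(sleep_records) == 0L) {
    out <- data.frame(participant_id = character(), night = as.Date(character()),
                      rem_s = numeric(), core_s = numeric(), deep_s = numeric(),
                      awake_s = numeric(), sleep_total_s = numeric())
    attr(out, "empty_nights") <- as.Date(character())
    return(out)
  }
  mid <- sleep_records$start + as.numeric(sleep_records$end - sleep_records$start, units = "secs") / 2
  # evening date of the window containing the midpoint: if the clock time is
  # before window_end the episode belongs to the previous evening
  midmin <- as.numeric(format(mid, "%H")) * 60 + as.numeric(format(mid, "%M"))
  night <- as.Date(format(mid, "%Y-%m-%d")) - (midmin < params$window_end_min)
  merged_any <- FALSE
  rows <- list()
  for (nt in as.list(sort(unique(night)))) {
    sel <- which(night == nt)
    sums <- c(rem = 0, core = 0, deep = 0, awake = 0)
    for (st in names(sums)) {
      ss <- sel[sleep_records$stage[sel] == st]
      if (!length(ss)) next
      m <- cbind(as.numeric(sleep_records$start[ss]), as.numeric(sleep_records$end[ss]))
      mm <- merge_intervals(m)
      if (sum(mm[, 2] - mm[, 1]) < sum(m[, 2] - m[, 1])) merged_any <- TRUE
      sums[st] <- sum(mm[, 2] - mm[, 1])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = pid, night = nt, rem_s = sums["rem"], core_s = sums["core"],
      deep_s = sums["deep"], awake_s = sums["awake"],
      sleep_total_s = sums["rem"] + sums["core"] + sums["deep"],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (merged_any) warning("overlapping same-stage sleep records merged before summation")
  out <- do.call(rbind, rows)
  attr(out, "empty_nights") <- out$night[out$sleep_total_s == 0]
  out
}

#' Total smartphone use per day
#'
#' Pass-through of the coded daily totals with validation.
#'
#' @param daily_totals `daily` data.frame from [read_usage_table()].
#' @return data.frame `participant_id`, `date`, `tsu_s`.
#' @export
compute_tsu <- function(daily_totals) {
  if (any(daily_totals$seconds_used < 0, na.rm = TRUE)) stop("negative daily total")
  data.frame(participant_id = daily_totals$participant_id,
             date = daily_totals$date, tsu_s = daily_totals$seconds_used,
             stringsAsFactors = FALSE)
}

#' Smartphone use in bed per night
#'
#' For every clock hour overlapping an in-bed interval, the hour's coded usage
#' seconds are prorated by the fraction of the hour covered by the interval
#' (usage is assumed uniform within the hour) and summed over the interval.
#'
#' @param usage_hours `hourly` data.frame from [read_usage_table()].
#' @param inbed_intervals data.frame from [detect_inbed()].
#' @return data.frame `participant_id`, `night`, `suib_s` with one row per
#'   detected night (zero when no usage overlaps the interval).
#' @export
compute_suib <- function(usage_hours, inbed_intervals) {
  n <- nrow(inbed_intervals)
  suib <- numeric(n)
  if (n == 0) {
    return(data.frame(participant_id = character(), night = as.Date(character()),
                      suib_s = numeric()))
  }
  tz <- attr(inbed_intervals$enter, "tzone") %||% "UTC"
  hs <- as.POSIXct(paste(usage_hours$date, sprintf("%02d:00:00", usage_hours$hour)), tz = tz)
  hs_num <- as.numeric(hs)
  for (i in seq_len(n)) {
    sel <- usage_hours$participant_id == inbed_intervals$participant_id[i]
    if (!any(sel)) next
    a <- as.numeric(inbed_intervals$enter[i]); b <- as.numeric(inbed_intervals$exit[i])
    ov <- pmin(hs_num[sel] + 3600, b) - pmax(hs_num[sel], a)
    ov[ov < 0] <- 0
    suib[i] <- sum(usage_hours$seconds_used[sel] * ov / 3600)
  }
  data.frame(participant_id = inbed_intervals$participant_id,
             night = inbed_intervals$night, suib_s = suib, stringsAsFactors = FALSE)
}

#' Assemble the person-day analysis panel
#'
#' Joins per-day total use, per-night in-bed use and per-night sleep sums on
#' the day-index grid. In-bed use is capped at the day's total use; nights the
#' detector flagged missing carry missing in-bed use, detected nights with no
#' overlapping usage carry zero.
#'
#' @param participants character vector of ids.
#' @param start_date first study date (day index 1).
#' @param n_days panel length (days).
#' @param sleep_daily row-bound output of [aggregate_sleep()].
#' @param tsu_daily output of [compute_tsu()].
#' @param suib_nightly output of [compute_suib()].
#' @param missing_nights optional data.frame `participant_id`, `night` of
#'   nights flagged missing by the detector.
#' @return panel data.frame in the [write_panel()] layout.
#' @export
build_panel <- function(participants, start_date, n_days,
                        sleep_daily, tsu_daily, suib_nightly,
                        missing_nights = NULL) {
  start_date <- as.Date(start_date)
  grid <- expand.grid(participant_id = participants, day_index = seq_len(n_days),
                      stringsAsFactors = FALSE)
  grid$date <- start_date + grid$day_index - 1L
  key <- function(p, d) paste(p, d)
  sk <- key(sleep_daily$participant_id, sleep_daily$night)
  tk <- key(tsu_daily$participant_id, tsu_daily$date)
  uk <- key(suib_nightly$participant_id, suib_nightly$night)
  gk <- key(grid$participant_id, grid$date)
  si <- match(gk, sk); ti <- match(gk, tk); ui <- match(gk, uk)
  panel <- data.frame(grid,
                      tsu_s = tsu_daily$tsu_s[ti],
                      suib_s = suib_nightly$suib_s[ui],
                      sleep_total_s = sleep_daily$sleep_total_s[si],
                      rem_s = sleep_daily$rem_s[si],
                      core_s = sleep_daily$core_s[si],
                      deep_s = sleep_daily$deep_s[si],
                      stringsAsFactors = FALSE)
  # a detected night absent from the usage join means zero in-bed use; a night
  # the detector flagged missing stays missing
  detected <- gk %in% uk
  panel$suib_s[!detected] <- NA_real_
  if (!is.null(missing_nights) && nrow(missing_nights)) {
    mk <- key(missing_nights$participant_id, missing_nights$night)
    panel$suib_s[gk %in% mk] <- NA_real_
  }
  panel$suib_s <- pmin(panel$suib_s, panel$tsu_s)
  panel <- panel[order(panel$participant_id, panel$day_index), ]
  rownames(panel) <- NULL
  panel
}

#' Apply the missing-data exclusion rule
#'
#' Removes participants with at least `max_missing_days` missing days on
#' either the sleep block or the screen-time block (the rule is inclusive:
#' exactly `max_missing_days` missing days excludes).
#'
#' @param panel person-day panel.
#' @param max_missing_days exclusion threshold in days.
#' @return list with the filtered `panel` and an `exclusions` data.frame
#'   (`participant_id`, `missing_sleep_days`, `missing_st_days`, `cause`).
#' @export
filter_missing <- function(panel, max_missing_days = 7) {
  miss <- stats::aggregate(cbind(sleep = is.na(panel$sleep_total_s),
                                 st = is.na(panel$tsu_s)) ~ participant_id,
                           data = panel, FUN = sum, na.action = stats::na.pass)
  bad_sleep <- miss$sleep >= max_missing_days
  bad_st <- miss$st >= max_missing_days
  out <- miss[bad_sleep | bad_st, , drop = FALSE]
  exclusions <- data.frame(participant_id = out$participant_id,
                           missing_sleep_days = out$sleep,
                           missing_st_days = out$st,
                           cause = ifelse(out$sleep >= max_missing_days & out$st >= max_missing_days,
                                          "both", ifelse(out$sleep >= max_missing_days, "sleep", "screen_time")),
                           stringsAsFactors = FALSE)
  keep <- !(panel$participant_id %in% exclusions$participant_id)
  panel <- panel[keep, , drop = FALSE]
  rownames(panel) <- NULL
  list(panel = panel, exclusions = exclusions)
}

#' Within/between decomposition with lag-1 copies
#'
#' For each analysis variable the observed series is split into a between
#' component (person mean, centered at the grand mean of person means) and a
#' within component (daily deviation from the person mean), and the same
#' decomposition is applied to the lagged copy of the series using the lagged
#' series' own observed person mean (days 1..T-1). Lags never cross
#' participants; day-1 rows are dropped. Participants with fewer than two
#' observed days on any requested variable cannot be lagged and are dropped
#' with a warning.
#'
#' @param panel person-day panel (typically filtered, possibly completed by
#'   imputation).
#' @param variables short variable names to decompose (subset of
#'   `c("tsu","suib","sleep","rem","core","deep")`).
#' @return object of class `decomposed_panel`: a data.frame with rows for day
#'   indices 2..T and, per variable `v`, columns `v_c` (grand-mean-centered
#'   value), `v_w`, `v_b` (within/between components) and `v_lw`, `v_lb`
#'   (within/between components of the lagged copy). Attribute `"sds"` holds
#'   the standardization scales (total, within, between per series).
#' @export
decompose_panel <- function(panel, variables = c("tsu", "suib", "sleep")) {
  stopifnot(all(variables %in% names(VAR_COLS)))
  panel <- panel[order(panel$participant_id, panel$day_index), ]
  pids <- unique(panel$participant_id)
  # drop participants that cannot be lagged on some requested variable
  nobs <- sapply(pids, function(p) {
    rows <- panel[panel$participant_id == p, ]
    min(sapply(variables, function(v) sum(!is.na(rows[[VAR_COLS[v]]]))))
  })
  if (any(nobs < 2)) {
    warning(sprintf("dropping %d participant(s) with < 2 observed days", sum(nobs < 2)))
    panel <- panel[panel$participant_id %in% pids[nobs >= 2], ]
    pids <- pids[nobs >= 2]
  }
  Tmax <- max(panel$day_index)
  rows <- panel[panel$day_index >= 2, c("participant_id", "day_index", "date")]
  sds <- list(); gms <- list()
  for (v in variables) {
    col <- VAR_COLS[v]
    cur <- panel[[col]]
    # person means: current series over all its observed days; lagged series
    # over its own observed days (1..T-1)
    pm_cur <- tapply(cur, panel$participant_id, function(x) mean(x, na.rm = TRUE))
    lag_sel <- panel$day_index <= Tmax - 1
    pm_lag <- tapply(cur[lag_sel], panel$participant_id[lag_sel],
                     function(x) mean(x, na.rm = TRUE))
    gm_cur <- mean(pm_cur, na.rm = TRUE); gm_lag <- mean(pm_lag, na.rm = TRUE)
    # align: row (p, t>=2) takes current value at t and lagged value at t-1
    idx_cur <- match(paste(rows$participant_id, rows$day_index),
                     paste(panel$participant_id, panel$day_index))
    idx_lag <- match(paste(rows$participant_id, rows$day_index - 1L),
                     paste(panel$participant_id, panel$day_index))
    val_cur <- cur[idx_cur]; val_lag <- cur[idx_lag]
    pmc <- as.numeric(pm_cur[rows$participant_id])
    pml <- as.numeric(pm_lag[rows$participant_id])
    rows[[paste0(v, "_c")]] <- val_cur - gm_cur
    rows[[paste0(v, "_w")]] <- val_cur - pmc
    rows[[paste0(v, "_b")]] <- pmc - gm_cur
    rows[[paste0(v, "_lw")]] <- val_lag - pml
    rows[[paste0(v, "_lb")]] <- pml - gm_lag
    sds[[v]] <- c(tot = stats::sd(rows[[paste0(v, "_c")]], na.rm = TRUE),
                  w = stats::sd(rows[[paste0(v, "_w")]], na.rm = TRUE),
                  b = stats::sd(unique(data.frame(p = rows$participant_id,
                                                  b = rows[[paste0(v, "_b")]]))$b, na.rm = TRUE),
                  lw = stats::sd(rows[[paste0(v, "_lw")]], na.rm = TRUE),
                  lb = stats::sd(unique(data.frame(p = rows$participant_id,
                                                   b = rows[[paste0(v, "_lb")]]))$b, na.rm = TRUE))
    gms[[v]] <- c(cur = gm_cur, lag = gm_lag)
  }
  rownames(rows) <- NULL
  structure(rows, sds = sds, grand_means = gms, variables = variables,
            class = c("decomposed_panel", "data.frame"))
}
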