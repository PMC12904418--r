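# Fixture builders and independent brute-force oracles used across the suite.

TZ <- "Europe/Brussels"

hk_xml <- function(records) {
  body <- vapply(records, function(r)
    sprintf('<Record type="%s" sourceName="watch" value="%s" startDate="%s" endDate="%s"/>',
            r$type, r$value, r$start, r$end), character(1))
  paste(c('<?xml version="1.0"?>', "<HealthData>", body, "</HealthData>"), collapse = "\n")
}

sleep_rec <- function(value, start, end)
  list(type = "HKCategoryTypeIdentifierSleepAnalysis", value = value, start = start, end = end)

step_rec <- function(steps, start, end)
  list(type = "HKQuantityTypeIdentifierStepCount", value = steps, start = start, end = end)

# step records realizing a given active/inactive epoch pattern on a 10-minute
# grid starting at `t0`; active epochs get `active_steps`, inactive 0,
# NA epochs get no record (no coverage)
steps_from_pattern <- function(pattern, t0, participant = "p1", active_steps = 100,
                               epoch_minutes = 10) {
  el <- epoch_minutes * 60
  rows <- lapply(seq_along(pattern), function(i) {
    if (is.na(pattern[i])) return(NULL)
    data.frame(participant_id = participant,
               start = t0 + (i - 1) * el, end = t0 + i * el,
               steps = if (pattern[i]) active_steps else 0)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# brute-force in-bed run finder: enumerate all candidate spans on the epoch
# activity string and apply the rules directly (low endpoints, interior
# active bursts short enough for WASO and below the exit-confirmation
# length, minimum duration); pick the longest span, earliest on ties.
oracle_inbed_run <- function(active, params) {
  act <- ifelse(is.na(active), FALSE, active)
  n <- length(act)
  min_ep <- ceiling(params$min_inbed_hours * 60 / params$epoch_minutes)
  best <- NULL
  for (i in seq_len(n)) {
    if (act[i]) next
    for (j in i:n) {
      if (act[j]) next
      if (j - i + 1 < min_ep) next
      seg <- act[i:j]
      r <- rle(seg)
      bursts <- r$lengths[r$values]
      ok <- !length(bursts) ||
        all(bursts <= params$max_waso_epochs & bursts < params$confirm_exit_epochs)
      if (!ok) next
      span <- j - i + 1
      if (is.null(best) || span > best[3]) best <- c(i, j, span)
    }
  }
  best
}

# second-resolution rasterization oracle for step apportionment
oracle_epoch_sum <- function(step_records, t0, n_epochs, epoch_minutes = 10) {
  el <- epoch_minutes * 60
  grid <- numeric(n_epochs * el)          # one slot per second from t0
  for (i in seq_len(nrow(step_records))) {
    a <- as.numeric(step_records$start[i]) - as.numeric(t0)
    b <- as.numeric(step_records$end[i]) - as.numeric(t0)
    secs <- seq(a, b - 1)
    keep <- secs >= 0 & secs < length(grid)
    grid[secs[keep] + 1] <- grid[secs[keep] + 1] + step_records$steps[i] / (b - a)
  }
  sapply(seq_len(n_epochs), function(e) sum(grid[((e - 1) * el + 1):(e * el)]))
}

# second-resolution oracle for in-bed usage proration
oracle_suib <- function(usage_hours, enter, exit, tz = TZ) {
  total <- 0
  for (i in seq_len(nrow(usage_hours))) {
    h0 <- as.numeric(as.POSIXct(paste(usage_hours$date[i],
                                      sprintf("%02d:00:00", usage_hours$hour[i])), tz = tz))
    ov <- min(h0 + 3600, as.numeric(exit)) - max(h0, as.numeric(enter))
    if (ov > 0) total <- total + usage_hours$seconds_used[i] * ov / 3600
  }
  total
}

# small complete panel with known values for decomposition tests
toy_panel <- function(values_by_participant, start_date = as.Date("2024-04-01")) {
  rows <- lapply(names(values_by_participant), function(p) {
    v <- values_by_participant[[p]]
    data.frame(participant_id = p, day_index = seq_along(v),
               date = start_date + seq_along(v) - 1,
               tsu_s = v, suib_s = v / 4, sleep_total_s = v * 2,
               rem_s = NA_real_, core_s = NA_real_, deep_s = NA_real_)
  })
  do.call(rbind, rows)
}

# cache for the expensive full-scale recovery fits shared by the acceptance
# blocks (computed once per test run, at the study's native scale)
recovery_cache <- new.env(parent = emptyenv())

recovery_fit <- function(model, seed = 1) {
  key <- paste0("m", model)
  if (!is.null(recovery_cache[[key]])) return(recovery_cache[[key]])
  vars <- if (model == 1) c("tsu", "suib", "sleep") else c("tsu", "suib", "core", "deep", "rem")
  cal <- calibrate_between(synth_config(model = model, seed = sleepscreen:::derive_seed(seed, paste0("study", model))),
                           n_pop = 6000, seed = sleepscreen:::derive_seed(seed, paste0("cal", model)))
  sim <- simulate_panel(cal)
  kept <- filter_missing(sim$panel)
  imp <- impute_panel(kept$panel, variables = vars, m = 5,
                      seed = sleepscreen:::derive_seed(seed, paste0("imp", model)))
  fit <- dsem_fit(imp, dsem_spec(model), seed = sleepscreen:::derive_seed(seed, paste0("fit", model)))
  recovery_cache[[key]] <- list(fit = fit, truth = sim$truth, config = cal)
  recovery_cache[[key]]
}
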