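mk_sleep <- function(stage, start, end, pid = "p1") {
  data.frame(participant_id = pid, stage = stage,
             start = as.POSIXct(start, tz = TZ), end = as.POSIXct(end, tz = TZ),
             stringsAsFactors = FALSE)
}

test_that("sleep aggregation sums stages per night and excludes awake", {
  recs <- rbind(
    mk_sleep("core", "2024-04-01 23:30:00", "2024-04-02 04:28:48"),   # 4.98 h
    mk_sleep("deep", "2024-04-02 04:28:48", "2024-04-02 05:12:36"),   # 0.73 h
    mk_sleep("rem",  "2024-04-02 05:12:36", "2024-04-02 06:45:36"),   # 1.55 h
    mk_sleep("awake", "2024-04-02 02:00:00", "2024-04-02 02:10:00"))
  agg <- aggregate_sleep(recs)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$night, as.Date("2024-04-01"))
  expect_equal(agg$sleep_total_s / 3600, 7.26, tolerance = 1e-9)
  expect_equal(agg$core_s / 3600, 4.98, tolerance = 1e-9)
  expect_equal(agg$awake_s / 3600, 1 / 6, tolerance = 1e-9)

  one <- aggregate_sleep(mk_sleep("core", "2024-04-01 22:00:00", "2024-04-02 06:00:00"))
  expect_equal(one$sleep_total_s, one$core_s)
  expect_equal(one$sleep_total_s / 3600, 8)

  only_awake <- aggregate_sleep(mk_sleep("awake", "2024-04-02 03:00:00", "2024-04-02 03:30:00"))
  expect_equal(only_awake$sleep_total_s, 0)
  expect_equal(attr(only_awake, "empty_nights"), only_awake$night)
})

test_that("overlapping same-stage records are merged with a warning", {
  recs <- rbind(mk_sleep("core", "2024-04-01 23:00:00", "2024-04-02 01:00:00"),
                mk_sleep("core", "2024-04-02 00:30:00", "2024-04-02 02:00:00"))
  expect_warning(agg <- aggregate_sleep(recs), "merged")
  expect_equal(agg$core_s / 3600, 3)   # union, not sum
})

test_that("daily totals pass through with validation", {
  dt <- data.frame(participant_id = "p1", date = as.Date("2024-03-01"), seconds_used = 13860)
  expect_equal(compute_tsu(dt)$tsu_s / 3600, 3.85)
  dt$seconds_used <- 0
  expect_equal(compute_tsu(dt)$tsu_s, 0)
  dt$seconds_used <- -1
  expect_error(compute_tsu(dt), "negative")
})

test_that("in-bed usage is prorated by hour overlap", {
  iv <- data.frame(participant_id = "p1", night = as.Date("2024-04-01"),
                   enter = as.POSIXct("2024-04-01 23:30:00", tz = TZ),
                   exit = as.POSIXct("2024-04-02 07:00:00", tz = TZ))
  # hour fully inside
  u1 <- data.frame(participant_id = "p1", date = as.Date("2024-04-02"),
                   hour = 1L, seconds_used = 1800)
  expect_equal(compute_suib(u1, iv)$suib_s, 1800)
  # interval covers half of hour 23 -> 600 s becomes 300
  u2 <- data.frame(participant_id = "p1", date = as.Date("2024-04-01"),
                   hour = 23L, seconds_used = 600)
  expect_equal(compute_suib(u2, iv)$suib_s, 300)
  # boundary hours combined: 600 in hour 23 (half) + 900 in hour 6 (full)
  u3 <- rbind(u2, data.frame(participant_id = "p1", date = as.Date("2024-04-02"),
                             hour = 6L, seconds_used = 900))
  expect_equal(compute_suib(u3, iv)$suib_s, 1200)
  expect_equal(compute_suib(u3, iv)$suib_s,
               oracle_suib(u3, iv$enter, iv$exit), tolerance = 1e-9)
})

test_that("prorated in-bed use never exceeds usage or interval duration", {
  set.seed(77)
  for (rep in 1:50) {
    enter <- as.POSIXct("2024-04-01 20:00:00", tz = TZ) + sample(0:360, 1) * 60
    exit <- enter + sample(180:720, 1) * 60
    iv <- data.frame(participant_id = "p1", night = as.Date("2024-04-01"),
                     enter = enter, exit = exit)
    hours <- sample(0:23, 8)
    u <- data.frame(participant_id = "p1",
                    date = as.Date("2024-04-01") + rep(0:1, 4)[seq_along(hours)],
                    hour = hours, seconds_used = sample(0:3600, 8))
    s <- compute_suib(u, iv)$suib_s
    expect_lte(s, sum(u$seconds_used) + 1e-9)
    expect_lte(s, as.numeric(exit - enter, units = "secs") + 1e-9)
    expect_equal(s, oracle_suib(u, enter, exit), tolerance = 1e-9)
  }
})

test_that("exclusion rule removes participants at or above the threshold", {
  # constructed cohort of 76: 5 with >= 7 missing sleep days (one exactly 7),
  # 3 with >= 7 missing screen-time days
  set.seed(1)
  panels <- lapply(1:76, function(i) {
    v <- abs(rnorm(14, 10000, 2000))
    p <- toy_panel(setNames(list(v), sprintf("p%02d", i)))
    if (i <= 4) p$sleep_total_s[1:8] <- NA
    if (i == 5) p$sleep_total_s[1:7] <- NA
    if (i %in% 6:8) p$tsu_s[1:9] <- NA
    p
  })
  panel <- do.call(rbind, panels)
  out <- filter_missing(panel, max_missing_days = 7)
  expect_equal(length(unique(out$panel$participant_id)), 68)
  expect_equal(nrow(out$exclusions), 8)
  expect_setequal(out$exclusions$cause[out$exclusions$participant_id == "p05"], "sleep")
  # idempotence
  again <- filter_missing(out$panel, max_missing_days = 7)
  expect_identical(again$panel, out$panel)
  expect_equal(nrow(again$exclusions), 0)
  # participants with 6 missing days stay
  p6 <- toy_panel(list(keep = abs(rnorm(14, 1, .1)) * 3600))
  p6$sleep_total_s[1:6] <- NA
  expect_equal(nrow(filter_missing(p6)$exclusions), 0)
})

test_that("decomposition splits person means and within deviations", {
  p <- toy_panel(list(a = c(2, 4, 6)))
  d <- decompose_panel(p, variables = "tsu")
  # person mean 4 over all observed days; within components -2, 0, 2
  expect_equal(d$tsu_w + (4 - mean(4)), c(0, 2) + 0)   # rows t = 2, 3
  expect_equal(d$tsu_w, c(0, 2))
  expect_equal(unique(d$tsu_b), 0)                     # single participant: pm == gm
  # identity: centered value = within + between, exactly
  expect_identical(d$tsu_c, d$tsu_w + d$tsu_b)
})

test_that("a constant series has zero within components", {
  p <- toy_panel(list(a = rep(5, 14), b = rep(9, 14)))
  d <- decompose_panel(p, variables = "tsu")
  expect_true(all(d$tsu_w == 0))
  expect_equal(unique(d$tsu_b), c(5, 9) - 7)
})

test_that("lag-complete row count is participants x (days - 1)", {
  cfg <- synth_config(n_participants = 68, missing_sleep = 0, missing_st = 0, seed = 8)
  d <- decompose_panel(simulate_panel(cfg)$panel)
  expect_equal(nrow(d), 68 * 13)
})

test_that("within components sum to zero per participant on complete data", {
  cfg <- synth_config(n_participants = 12, missing_sleep = 0, missing_st = 0, seed = 9)
  panel <- simulate_panel(cfg)$panel
  d <- decompose_panel(panel)
  # current-series person means cover all 14 days; within sums over days 2..14
  # equal minus the day-1 deviation
  for (v in c("tsu", "suib", "sleep")) {
    col <- sleepscreen:::VAR_COLS[v]
    day1 <- panel[panel$day_index == 1, ]
    pm <- tapply(panel[[col]], panel$participant_id, mean)
    sums <- as.numeric(tapply(d[[paste0(v, "_w")]], d$participant_id, sum))
    expect_equal(sums + (day1[[col]] - as.numeric(pm[day1$participant_id])),
                 rep(0, 12), tolerance = 1e-9)
    # and the lagged series (days 1..13) sums to zero outright
    lsums <- as.numeric(tapply(d[[paste0(v, "_lw")]], d$participant_id, sum))
    expect_equal(lsums, rep(0, 12), tolerance = 1e-9)
  }
})

test_that("lags never cross participants and match a pairing oracle", {
  set.seed(33)
  p <- toy_panel(list(a = rnorm(14, 100, 10), b = rnorm(14, 200, 30)))
  d <- decompose_panel(p, variables = "tsu")
  for (pid in c("a", "b")) {
    v <- p$tsu_s[p$participant_id == pid]
    rows <- d[d$participant_id == pid, ]
    # brute-force pairing: within(t) against within(t-1)
    expect_equal(rows$tsu_w, (v - mean(v))[2:14])
    expect_equal(rows$tsu_lw, (v - mean(v[1:13]))[1:13])
    r_pkg <- cor(rows$tsu_w, rows$tsu_lw)
    r_oracle <- cor((v - mean(v))[2:14], (v - mean(v[1:13]))[1:13])
    expect_equal(r_pkg, r_oracle)
  }
})

test_that("participants too short to lag are dropped with a warning", {
  p <- toy_panel(list(a = rnorm(14, 100, 5), b = c(3, rep(NA, 13))))
  expect_warning(d <- decompose_panel(p, variables = "tsu"), "2 observed")
  expect_false("b" %in% d$participant_id)
})

test_that("panel conservation: in-bed use never exceeds total use", {
  cfg <- synth_config(n_participants = 30, seed = 10)
  panel <- simulate_panel(cfg)$panel
  ok <- !is.na(panel$suib_s) & !is.na(panel$tsu_s)
  expect_true(all(panel$suib_s[ok] <= panel$tsu_s[ok] + 1e-9))
})
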