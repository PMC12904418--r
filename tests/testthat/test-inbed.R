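t_grid <- as.POSIXct("2024-04-01 20:00:00", tz = TZ)

test_that("step apportionment is proportional to epoch overlap", {
  p <- detector_params()
  one <- data.frame(participant_id = "p1", start = t_grid, end = t_grid + 600, steps = 100)
  ep <- epoch_steps(one, p)
  expect_equal(ep$steps[1], 100)

  two <- data.frame(participant_id = "p1", start = t_grid + 300, end = t_grid + 900, steps = 100)
  ep2 <- epoch_steps(two, p)
  expect_equal(ep2$steps, c(50, 50))
})

test_that("epoch sums match a second-resolution rasterization oracle", {
  p <- detector_params()
  recs <- data.frame(participant_id = "p1",
                     start = t_grid + c(0, 240, 1100),
                     end = t_grid + c(700, 1500, 1800),
                     steps = c(70, 126, 35))
  ep <- epoch_steps(recs, p)
  oracle <- oracle_epoch_sum(recs, t_grid, length(ep$steps))
  expect_equal(ep$steps, oracle, tolerance = 1e-8)
})

test_that("uncovered epochs are missing, not zero", {
  p <- detector_params()
  recs <- data.frame(participant_id = "p1",
                     start = c(t_grid, t_grid + 1800),
                     end = c(t_grid + 600, t_grid + 2400), steps = c(10, 0))
  ep <- epoch_steps(recs, p)
  expect_equal(ep$steps, c(10, NA, NA, 0))
})

make_night_series <- function(pattern) {
  recs <- steps_from_pattern(pattern, t_grid)
  epoch_steps(recs, detector_params())
}

test_that("a quiet night yields one interval with empty WASO", {
  # active 20:00-23:00, quiet 23:00-07:00, active 07:00-12:00
  pattern <- c(rep(TRUE, 18), rep(FALSE, 48), rep(TRUE, 30))
  iv <- detect_inbed(make_night_series(pattern))
  expect_equal(nrow(iv), 1)
  expect_equal(format(iv$enter, "%H:%M"), "23:00")
  expect_equal(format(iv$exit, "%H:%M"), "07:00")
  expect_equal(iv$n_waso, 0)
})

test_that("a short interior burst is absorbed as WASO", {
  pattern <- c(rep(TRUE, 18), rep(FALSE, 48), rep(TRUE, 30))
  pattern[18 + 25:26] <- TRUE   # 2 active epochs at 03:00-03:20
  iv <- detect_inbed(make_night_series(pattern))
  expect_equal(nrow(iv), 1)
  expect_equal(format(iv$enter, "%H:%M"), "23:00")
  expect_equal(format(iv$exit, "%H:%M"), "07:00")
  expect_equal(iv$n_waso, 1)
  w <- iv$waso[[1]]
  expect_equal(format(w$start, "%H:%M"), "03:00")
  expect_equal(format(w$end, "%H:%M"), "03:20")
})

test_that("a fully active night yields no interval and a flagged night", {
  iv <- detect_inbed(make_night_series(rep(TRUE, 96)))
  expect_equal(nrow(iv), 0)
  expect_length(attr(iv, "missing_nights"), 1)
})

test_that("an entirely uncovered window flags the night as missing", {
  # coverage only in the afternoon before and after; the 20:00-12:00 window
  # itself has no device coverage at all
  t0 <- as.POSIXct("2024-04-01 14:00:00", tz = TZ)
  pattern <- c(rep(TRUE, 6), rep(NA, 131), TRUE)   # 14:00-15:00 and 12:50-13:00 next day
  recs <- steps_from_pattern(pattern, t0)
  iv <- detect_inbed(epoch_steps(recs, detector_params()))
  expect_equal(nrow(iv), 0)
  expect_true(as.Date("2024-04-01") %in% attr(iv, "missing_nights"))
})

test_that("coverage gaps inside the window count as inactivity evidence", {
  # active evening, one covered quiet epoch at 23:00 and one at 06:50, the
  # night in between uncovered: the gap is read as a sustained quiet period
  pattern <- c(rep(TRUE, 18), FALSE, rep(NA, 46), FALSE, rep(TRUE, 30))
  iv <- detect_inbed(make_night_series(pattern))
  expect_equal(nrow(iv), 1)
  expect_equal(format(iv$enter, "%H:%M"), "23:00")
  expect_equal(format(iv$exit, "%H:%M"), "07:00")
})

test_that("detection matches brute-force enumeration on random epoch strings", {
  set.seed(404)
  param_sets <- list(detector_params(),
                     detector_params(max_waso_epochs = 2, confirm_exit_epochs = 4),
                     detector_params(min_inbed_hours = 2, confirm_exit_epochs = 2))
  for (rep in 1:120) {
    p <- param_sets[[1 + rep %% 3]]
    n <- sample(10:100, 1)
    active <- sample(c(TRUE, FALSE, NA), n, replace = TRUE, prob = c(.4, .5, .1))
    got <- sleepscreen:::find_inbed_run(active, p)
    want <- oracle_inbed_run(active, p)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(c(got$i, got$j), want[1:2],
                   info = paste("pattern:", paste(as.integer(active), collapse = "")))
    }
  }
})

test_that("WASO sub-intervals stay inside the interval and pairwise disjoint", {
  set.seed(505)
  for (rep in 1:300) {
    active <- sample(c(TRUE, FALSE), 96, replace = TRUE, prob = c(.35, .65))
    run <- sleepscreen:::find_inbed_run(active, detector_params())
    if (is.null(run) || !nrow(run$waso)) next
    expect_true(all(run$waso[, 1] > run$i & run$waso[, 2] < run$j))
    if (nrow(run$waso) > 1) {
      o <- order(run$waso[, 1])
      expect_true(all(run$waso[o, 1][-1] > run$waso[o, 2][-nrow(run$waso)]))
    }
  }
})

test_that("raising the low-step threshold never shortens the detected interval", {
  set.seed(606)
  pattern <- sample(c(TRUE, FALSE), 96, replace = TRUE, prob = c(.3, .7))
  recs <- steps_from_pattern(pattern, t_grid, active_steps = 8)
  prev_len <- 0
  for (thr in c(5, 9, 20)) {
    iv <- detect_inbed(epoch_steps(recs, detector_params()),
                       detector_params(low_step_threshold = thr))
    len <- if (nrow(iv)) as.numeric(iv$exit[1] - iv$enter[1], units = "mins") else 0
    expect_gte(len, prev_len)
    prev_len <- len
  }
})

test_that("detection is deterministic", {
  pattern <- c(rep(TRUE, 20), rep(FALSE, 40), rep(TRUE, 36))
  a <- detect_inbed(make_night_series(pattern))
  b <- detect_inbed(make_night_series(pattern))
  expect_identical(a$enter, b$enter)
  expect_identical(a$exit, b$exit)
})

test_that("coverage flags mark exactly the undetected nights", {
  pattern <- c(rep(TRUE, 18), rep(FALSE, 48), rep(TRUE, 30))
  iv <- detect_inbed(make_night_series(pattern))
  days <- data.frame(participant_id = "p1",
                     night = as.Date("2024-04-01") + 0:2)
  cov <- inbed_coverage(iv, days)
  expect_equal(cov$present, c(TRUE, FALSE, FALSE))
  cov0 <- inbed_coverage(iv[0, ], days)
  expect_false(any(cov0$present))
})
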