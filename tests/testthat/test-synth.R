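test_that("panel simulation is reproducible under a fixed seed", {
  a <- simulate_panel(synth_config(n_participants = 10, seed = 77))
  b <- simulate_panel(synth_config(n_participants = 10, seed = 77))
  expect_identical(a$panel, b$panel)
  c <- simulate_panel(synth_config(n_participants = 10, seed = 78))
  expect_false(identical(a$panel$tsu_s, c$panel$tsu_s))
})

test_that("zero dynamics give white-noise within components", {
  zero <- matrix(0, 3, 3, dimnames = list(c("tsu", "suib", "sleep"),
                                          c("tsu", "suib", "sleep")))
  cfg <- synth_config(model = 1, n_participants = 68, A = zero, C = zero,
                      missing_sleep = 0, missing_st = 0, seed = 79)
  d <- decompose_panel(simulate_panel(cfg)$panel)
  for (v in c("tsu", "suib", "sleep")) {
    r <- cor(d[[paste0(v, "_w")]], d[[paste0(v, "_lw")]])
    # centering on the person's own mean induces a mechanical -1/(T-1) even
    # for white noise; the capped, softplus-bounded in-bed variable carries a
    # slightly larger artifact
    expect_lt(abs(r + 1 / 13), 0.08)
    if (v != "suib") expect_lt(abs(r), 0.1)
  }
})

test_that("non-stationary dynamics are rejected at construction", {
  A <- matrix(0, 3, 3, dimnames = list(c("tsu", "suib", "sleep"),
                                       c("tsu", "suib", "sleep")))
  diag(A) <- 1.2
  expect_error(synth_config(model = 1, A = A), "stationary")
})

test_that("a non-triangular contemporaneous matrix is rejected", {
  C <- matrix(0, 3, 3, dimnames = list(c("tsu", "suib", "sleep"),
                                       c("tsu", "suib", "sleep")))
  C["tsu", "sleep"] <- 0.2   # sleep is downstream of total use in the causal order
  expect_error(synth_config(model = 1, C = C), "lower triangular")
})

test_that("simulated margins match the configured anchors at scale", {
  cfg <- synth_config(model = 2, n_participants = 10000,
                      missing_sleep = 0, missing_st = 0, seed = 80)
  panel <- simulate_panel(cfg)$panel
  checks <- list(tsu = "tsu_s", suib = "suib_s", core = "core_s",
                 deep = "deep_s", rem = "rem_s")
  for (v in names(checks)) {
    m <- mean(panel[[checks[[v]]]]) / 3600
    s <- sd(panel[[checks[[v]]]]) / 3600
    a <- sleepscreen:::DEFAULT_ANCHORS[[v]]
    # the in-bed <= total cap shaves the top of the in-bed distribution;
    # 2% on the mean, slightly wider on the clipped SD
    expect_lt(abs(m / a["mean"] - 1), 0.02)
    expect_lt(abs(s / a["sd"] - 1), if (v == "suib") 0.05 else 0.02)
  }
})

test_that("in-bed/total capping is rare or flagged in the truth record", {
  sim <- simulate_panel(synth_config(n_participants = 68, seed = 81))
  expect_true(sim$truth$cap_rate < 0.05 || isTRUE(sim$truth$cap_flag))
  expect_lt(sim$truth$cap_rate, 0.10)
})

test_that("between-level targets at or beyond one are rejected", {
  expect_error(calibrate_between(synth_config(model = 1, seed = 82),
                                 target_betas = c(tsu = 1.0, suib = 0.6, sleep = 0.5)),
               "infeasible")
})

test_that("an unreachably small stability target reports the feasible floor", {
  cfg <- synth_config(model = 1, seed = 83)
  cal <- calibrate_between(cfg, target_betas = c(tsu = 0.82, suib = 0.63, sleep = 0.01),
                           n_pop = 1500, max_iter = 4, seed = 84)
  expect_true(cal$calibration$feasible_floor_hit)
  # overlapping 13-day person means of the same series share almost all their
  # days; their association cannot be pushed to zero
  expect_gt(cal$calibration$achieved_between["sleep"], 0.05)
})

test_that("calibration reproduces the stability targets in an independent cohort", {
  cfg <- synth_config(model = 1, seed = 85)
  cal <- calibrate_between(cfg, n_pop = 4000, seed = 86)
  pop <- sleepscreen:::population_paths(cal, n_pop = 6000, seed = 87)
  for (v in c("tsu", "suib", "sleep"))
    expect_lt(abs(pop$between[v] - cal$between_targets[v]), 0.03)
  expect_lt(max(abs(pop$within - (cal$A + cal$C))), 0.03)
})

test_that("raw-stream emission validates in-bed versus total use", {
  sim <- simulate_panel(synth_config(n_participants = 2, seed = 88,
                                     missing_sleep = 0, missing_st = 0))
  bad <- sim$panel
  bad$suib_s[3] <- bad$tsu_s[3] + 100
  expect_error(simulate_raw(bad, synth_config(n_participants = 2, seed = 88)),
               "exceeding total use")
})

test_that("zero in-bed use places no usage inside the interval", {
  cfg <- synth_config(n_participants = 1, n_days = 3, seed = 89,
                      missing_sleep = 0, missing_st = 0)
  sim <- simulate_panel(cfg)
  sim$panel$suib_s <- 0
  raw <- simulate_raw(sim$panel, cfg)
  hourly <- raw$usage[raw$usage$hour != "daily", ]
  # every hourly row lies in the afternoon/evening block clear of the
  # nightly intervals (see emission preferences)
  expect_true(all(as.integer(hourly$hour) %in% c(9:22)))
  iv <- detect_inbed(epoch_steps(read_steps_xml(raw$steps_xml[[1]],
                                                names(raw$steps_xml)[1])))
  suib <- compute_suib(data.frame(participant_id = iv$participant_id[1],
                                  date = as.Date(hourly$date), hour = as.integer(hourly$hour),
                                  seconds_used = hourly$seconds), iv)
  expect_true(all(suib$suib_s < 1e-9))
})
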