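#!/usr/bin/env Rscript
# Simulate the synthetic study cohorts used throughout the analysis.
#
# Calibrates the generator so that the population fitted standardized paths
# equal the published point estimates (within level) and stability targets
# (between level), then draws one study per model at the study's native size
# (68 participants x 14 days, day-level missingness) and, for a 16-person
# subset, the raw device streams (watch XML + coded screen-time CSV).

suppressPackageStartupMessages(library(sleepscreen))
seed <- 20240401
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
ds <- function(tag) sleepscreen:::derive_seed(seed, tag)

for (model in 1:2) {
  message("Model ", model, ": calibrating generator (population n = 6000) ...")
  cal <- calibrate_between(synth_config(model = model, seed = ds(paste0("study", model))),
                           n_pop = 6000, seed = ds(paste0("cal", model)))
  stopifnot(cal$calibration$converged)
  message("  between-level stabilities achieved: ",
          paste(sprintf("%s=%.3f", names(cal$calibration$achieved_between),
                        cal$calibration$achieved_between), collapse = ", "))
  sim <- simulate_panel(cal)
  write_panel(sim$panel, file.path(out, sprintf("panel_model%d.csv", model)))
  jsonlite::write_json(
    list(icc = as.list(round(cal$icc, 4)),
         cap_rate = sim$truth$cap_rate, cap_flag = sim$truth$cap_flag,
         n_missing_sleep = sim$truth$n_missing_sleep,
         n_missing_st = sim$truth$n_missing_st, seed = seed),
    file.path(out, sprintf("truth_model%d.json", model)),
    auto_unbox = TRUE, pretty = TRUE)
}

message("Raw streams for a 16-person subset (watch XML + screen-time CSV) ...")
cfg_raw <- synth_config(model = 1, n_participants = 16, seed = ds("raw"))
cal_raw <- calibrate_between(cfg_raw, n_pop = 4000, seed = ds("cal-raw"))
sim_raw_panel <- simulate_panel(cal_raw)
raw <- simulate_raw(sim_raw_panel$panel, cal_raw)
paths <- write_raw(raw, file.path(out, "raw"))
write_panel(sim_raw_panel$panel, file.path(out, "panel_raw_subset.csv"))
message("wrote ", length(paths$sleep), " sleep XML, ", length(paths$steps),
        " steps XML, and ", nrow(raw$usage), " usage rows under ", out, "/raw")
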