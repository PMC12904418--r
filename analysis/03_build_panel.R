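#!/usr/bin/env Rscript
# Apply the cohort exclusion rule and the within/between decomposition to
# the Model-1 study panel, and summarize what enters the models.

suppressPackageStartupMessages(library(sleepscreen))
panel <- read_panel("results/synthetic/panel_model1.csv")

kept <- filter_missing(panel, max_missing_days = 7)
message("cohort: ", length(unique(panel$participant_id)), " -> ",
        length(unique(kept$panel$participant_id)), " participants after the ",
        ">=7-missing-days rule (", nrow(kept$exclusions), " excluded)")
jsonlite::write_json(kept$exclusions, "results/exclusions.json",
                     auto_unbox = TRUE, pretty = TRUE)

for (v in c("tsu_s", "suib_s", "sleep_total_s")) {
  x <- kept$panel[[v]] / 3600
  message(sprintf("%-14s M = %5.2f h, SD = %4.2f h, %2d%% missing",
                  v, mean(x, na.rm = TRUE), sd(x, na.rm = TRUE),
                  round(100 * mean(is.na(x)))))
}

dec <- decompose_panel(kept$panel)
sds <- attr(dec, "sds")
for (v in c("tsu", "suib", "sleep"))
  message(sprintf("%-6s within SD %5.2f h | between SD %5.2f h | ICC-like share %.2f",
                  v, sds[[v]]["w"] / 3600, sds[[v]]["b"] / 3600,
                  sds[[v]]["b"]^2 / (sds[[v]]["b"]^2 + sds[[v]]["w"]^2)))
write_panel(kept$panel, "results/panel_filtered.csv")
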