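#!/usr/bin/env Rscript
# Fit the five-variable model (sleep split into core/deep/REM stages) to the
# Model-2 study panel.

suppressPackageStartupMessages(library(sleepscreen))
panel <- read_panel("results/synthetic/panel_model2.csv")
kept <- filter_missing(panel, max_missing_days = 7)

imp <- impute_panel(kept$panel, variables = c("tsu", "suib", "core", "deep", "rem"),
                    m = 5, seed = 21)
fit <- dsem_fit(imp, dsem_spec(2), seed = 22)
print(fit)
write.csv(fit$estimates, "results/model2_estimates.csv", row.names = FALSE)
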