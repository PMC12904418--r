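# Model specification for the two-level dynamic structural equation models
# and construction of the per-outcome design quantities.
#
# Timing rule at the within level: autoregressive paths are lagged; the paths
# from total use to every sleep outcome, from in-bed use to every sleep
# outcome, and from total use to in-bed use are contemporaneous ("current");
# every remaining cross path is lagged. Current paths are recursive in the
# causal order total use -> in-bed use -> sleep, so they form no cycle. Each
# within-level predictor has a matching between-level person-mean predictor
# of the same series (current-series mean for current paths, lagged-series
# mean for lagged paths).

MODEL_VARS <- list(`1` = c("tsu", "suib", "sleep"),
                   `2` = c("tsu", "suib", "core", "deep", "rem"))
SLEEP_VARS <- c("sleep", "core", "deep", "rem")

timing_map <- function(vars) {
  tm <- matrix("lagged", length(vars), length(vars),
               dimnames = list(outcome = vars, predictor = vars))
  for (o in intersect(vars, SLEEP_VARS)) tm[o, c("tsu", "suib")] <- "current"
  if (all(c("tsu", "suib") %in% vars)) tm["suib", "tsu"] <- "current"
  tm
}

#' Specify a two-level dynamic structural equation model
#'
#' Model 1 carries total sleep, total smartphone use and in-bed smartphone
#' use; Model 2 replaces total sleep by the three sleep stages.
#'
#' @param model 1 or 2.
#' @param chains number of MCMC chains.
#' @param iter iterations per chain (first half is warmup).
#' @param prior_beta_sd normal prior SD on standardized coefficients.
#' @param prior_scale_df,prior_scale half-Student-t prior (df, scale) on the
#'   residual and random-intercept SDs.
#' @param residual_correlation reserved flag; residuals across outcomes are
#'   independent given the random intercepts (the only implemented option).
#' @return object of class `dsem_spec`.
#' @export
dsem_spec <- function(model = 1, chains = 2, iter = 5000,
                      prior_beta_sd = 10, prior_scale_df = 3, prior_scale = 2.5,
                      residual_correlation = FALSE) {
  model <- as.character(model)
  if (!model %in% names(MODEL_VARS)) stop("model must be 1 or 2")
  if (isTRUE(residual_correlation)) stop("residual correlations are not implemented")
  vars <- MODEL_VARS[[model]]
  structure(list(model = as.integer(model), outcomes = vars,
                 timing = timing_map(vars), chains = chains, iter = iter,
                 warmup = floor(iter / 2),
                 prior = list(beta_sd = prior_beta_sd, scale_df = prior_scale_df,
                              scale = prior_scale)),
            class = "dsem_spec")
}

#' @export
print.dsem_spec <- function(x, ...) {
  cat("dsem_spec: Model", x$model, "| outcomes:", paste(x$outcomes, collapse = ", "),
      "|", x$chains, "chains x", x$iter, "iterations\n")
  print(x$timing)
  invisible(x)
}

#' Build standardized per-outcome design quantities
#'
#' For each outcome the within-level columns carry the predictor's within
#' component at the specified timing, standardized by the pooled
#' within-person SD; the matching between-level columns carry the
#' corresponding person means, standardized by the between-person SD of
#' person means. The outcome is the grand-mean-centered variable standardized
#' by its total SD over design rows, so coefficients are on the conventional
#' standardized-beta scale. Rows with any missing required cell are dropped
#' (after imputation that is only day-1 rows, which are absent by
#' construction).
#'
#' @param spec a [dsem_spec()].
#' @param decomposed a [decompose_panel()] result containing every model
#'   variable.
#' @return named list (one element per outcome) with `y`, `Xw`, `Xb`,
#'   `person` (factor), and a `labels` data.frame mapping columns to
#'   (predictor, timing, level).
#' @export
build_design <- function(spec, decomposed) {
  vars <- spec$outcomes
  missing_vars <- setdiff(vars, attr(decomposed, "variables"))
  if (length(missing_vars))
    stop("decomposed panel lacks model variable(s): ", paste(missing_vars, collapse = ", "))
  sds <- attr(decomposed, "sds")
  out <- list()
  for (o in vars) {
    y_raw <- decomposed[[paste0(o, "_c")]]
    Xw <- matrix(NA_real_, nrow(decomposed), length(vars))
    Xb <- matrix(NA_real_, nrow(decomposed), length(vars))
    labels <- data.frame(predictor = vars, timing = spec$timing[o, vars],
                         stringsAsFactors = FALSE)
    for (j in seq_along(vars)) {
      p <- vars[j]
      if (labels$timing[j] == "current") {
        Xw[, j] <- decomposed[[paste0(p, "_w")]] / sds[[p]]["w"]
        Xb[, j] <- decomposed[[paste0(p, "_b")]] / sds[[p]]["b"]
      } else {
        Xw[, j] <- decomposed[[paste0(p, "_lw")]] / sds[[p]]["lw"]
        Xb[, j] <- decomposed[[paste0(p, "_lb")]] / sds[[p]]["lb"]
      }
    }
    colnames(Xw) <- paste0(vars, "_", substr(labels$timing, 1, 3), "_w")
    colnames(Xb) <- paste0(vars, "_", substr(labels$timing, 1, 3), "_b")
    y <- y_raw / sds[[o]]["tot"]
    keep <- !is.na(y) & stats::complete.cases(Xw) & stats::complete.cases(Xb)
    out[[o]] <- list(y = y[keep], Xw = Xw[keep, , drop = FALSE],
                     Xb = Xb[keep, , drop = FALSE],
                     person = factor(decomposed$participant_id[keep]),
                     day_index = decomposed$day_index[keep],
                     labels = labels)
  }
  out
}
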