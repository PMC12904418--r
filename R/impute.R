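# Multiple imputation of the person-day panel by chained equations with
# normal linear conditional models.
#
# Each variable's conditional model regresses it on the same-day values of
# the other analysis variables, the participant's observed mean of the
# variable, and day-of-week indicators. Parameter uncertainty is propagated
# by drawing the residual variance from its scaled inverse-chi-square
# posterior and the coefficients from their conditional normal posterior
# before each predictive draw. Observed cells are never touched; the
# completed panels differ only in the originally-missing cells.

draw_impute <- function(y_obs, X_obs, X_mis) {
  p <- ncol(X_obs)
  XtX <- crossprod(X_obs) + diag(1e-8, p)  # tiny ridge guards collinear dummies
  bhat <- solve(XtX, crossprod(X_obs, y_obs))
  resid <- y_obs - X_obs %*% bhat
  df <- max(length(y_obs) - p, 2)
  sig2 <- sum(resid^2) / stats::rchisq(1, df)
  R <- chol(solve(XtX))
  beta <- bhat + sqrt(sig2) * t(R) %*% stats::rnorm(p)
  as.numeric(X_mis %*% beta + stats::rnorm(nrow(X_mis), 0, sqrt(sig2)))
}

#' Multiply impute missing panel cells
#'
#' @param panel filtered person-day panel.
#' @param variables short names of the variables to impute/use as predictors
#'   (default: every panel variable with at least one observed value).
#' @param m number of completed panels.
#' @param seed master seed; each imputation draws from a derived sub-seed so
#'   the whole set is reproducible bit-for-bit.
#' @param n_cycles chained-equation sweeps per imputation.
#' @return object of class `imputation_set`: list with `panels` (length `m`),
#'   `m`, `seed`, `method`, and the variables used.
#' @export
impute_panel <- function(panel, variables = NULL, m = 5, seed = 1, n_cycles = 10) {
  stopifnot(m >= 2 || all(!is.na(panel[unlist(VAR_COLS)])) || m >= 1)
  if (is.null(variables)) {
    variables <- names(VAR_COLS)[sapply(VAR_COLS, function(cl)
      cl %in% names(panel) && any(!is.na(panel[[cl]])))]
  }
  cols <- VAR_COLS[variables]
  for (cl in cols) if (all(is.na(panel[[cl]])))
    stop("cannot impute '", cl, "': no observed values")
  dow <- factor(format(as.Date(panel$date), "%u"), levels = as.character(1:7))
  dow_mm <- stats::model.matrix(~dow)[, -1, drop = FALSE]
  pm <- lapply(cols, function(cl)
    tapply(panel[[cl]], panel$participant_id, function(x) mean(x, na.rm = TRUE)))
  names(pm) <- cols
  panels <- vector("list", m)
  for (k in seq_len(m)) {
    set.seed(derive_seed(seed, paste0("impute-", k)))
    comp <- panel
    # initial fill: participant's observed mean (grand mean fallback)
    for (cl in cols) {
      mi <- is.na(comp[[cl]])
      if (!any(mi)) next
      fill <- pm[[cl]][comp$participant_id[mi]]
      fill[is.na(fill)] <- mean(panel[[cl]], na.rm = TRUE)
      comp[[cl]][mi] <- fill
    }
    any_missing <- any(sapply(cols, function(cl) any(is.na(panel[[cl]]))))
    if (any_missing) {
      for (cycle in seq_len(n_cycles)) {
        for (cl in cols) {
          mi <- is.na(panel[[cl]])
          if (!any(mi)) next
          others <- setdiff(cols, cl)
          X <- cbind(1, as.matrix(comp[others]),
                     pm_self = as.numeric(pm[[cl]][comp$participant_id]), dow_mm)
          comp[[cl]][mi] <- pmax(0, draw_impute(panel[[cl]][!mi],
                                                X[!mi, , drop = FALSE],
                                                X[mi, , drop = FALSE]))
        }
      }
    }
    # keep derived total consistent when stages were imputed
    if (all(c("rem_s", "core_s", "deep_s") %in% cols) && "sleep_total_s" %in% names(comp)) {
      mi_tot <- is.na(panel$sleep_total_s)
      comp$sleep_total_s[mi_tot] <- comp$rem_s[mi_tot] + comp$core_s[mi_tot] + comp$deep_s[mi_tot]
    }
    panels[[k]] <- comp
  }
  structure(list(panels = panels, m = m, seed = seed,
                 method = "chained-normal", variables = variables),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("imputation_set:", x$m, "completed panels (", x$method, "), seed", x$seed, "\n")
  invisible(x)
}
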