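# Synthetic study generator: the generative mirror of the fitted two-level
# model.
#
# Per participant, stable traits (between level) and a lag-1 structural
# vector-autoregression (within level) are simulated on a Gaussian latent
# scale with unit stationary variance per variable, combined as
#   latent_itv = mu_v + sqrt(icc_v) s_v trait_iv + sqrt(1-icc_v) s_v w_itv
# and mapped to non-negative durations (hours) through a softplus transform
# whose latent mean/SD (mu_v, s_v) are solved numerically so the observed
# margins match the configured anchors exactly. Contemporaneous paths are
# strictly lower-triangular in the causal order total use -> in-bed use ->
# sleep, so each day solves recursively.
#
# The coefficient matrices in the configuration are interpreted on the
# OBSERVED standardized scale (the scale of the fitted path estimates);
# `calibrate_between()` closes the loop, tuning the latent dynamics and the
# per-variable between/within variance ratios so the population fitted
# coefficients match the configured targets.

DEFAULT_ANCHORS <- list(tsu = c(mean = 3.85, sd = 2.34),
                        suib = c(mean = 0.54, sd = 0.73),
                        sleep = c(mean = 7.30, sd = 1.38),
                        core = c(mean = 4.98, sd = 1.16),
                        deep = c(mean = 0.73, sd = 0.35),
                        rem = c(mean = 1.55, sd = 0.57))

# printed standardized estimates used as default generating coefficients
model1_defaults <- function() {
  vars <- c("tsu", "suib", "sleep")
  A <- matrix(0, 3, 3, dimnames = list(vars, vars))
  C <- matrix(0, 3, 3, dimnames = list(vars, vars))
  A["tsu", c("tsu", "suib", "sleep")] <- c(0.00, 0.10, -0.05)
  A["suib", c("suib", "sleep")] <- c(0.01, 0.01)
  A["sleep", "sleep"] <- -0.16
  C["suib", "tsu"] <- 0.25
  C["sleep", c("tsu", "suib")] <- c(-0.02, 0.08)
  list(vars = vars, A = A, C = C,
       between = c(tsu = 0.82, suib = 0.63, sleep = 0.53),
       icc = c(tsu = 0.75, suib = 0.45, sleep = 0.28))
}

model2_defaults <- function() {
  vars <- c("tsu", "suib", "core", "deep", "rem")
  A <- matrix(0, 5, 5, dimnames = list(vars, vars))
  C <- matrix(0, 5, 5, dimnames = list(vars, vars))
  A["tsu", vars] <- c(0.00, 0.10, -0.05, 0.00, -0.01)
  A["suib", c("suib", "core", "deep", "rem")] <- c(0.01, -0.02, 0.03, -0.04)
  A["core", c("core", "deep", "rem")] <- c(-0.05, -0.03, -0.03)
  A["deep", c("core", "deep", "rem")] <- c(-0.07, -0.15, 0.01)
  A["rem", c("core", "deep", "rem")] <- c(-0.10, -0.02, -0.06)
  C["suib", "tsu"] <- 0.25
  C["core", c("tsu", "suib")] <- c(-0.03, 0.06)
  C["deep", c("tsu", "suib")] <- c(0.01, 0.03)
  C["rem", c("tsu", "suib")] <- c(0.02, 0.04)
  list(vars = vars, A = A, C = C,
       between = c(tsu = 0.82, suib = 0.63, core = 0.58, deep = 0.56, rem = 0.56),
       icc = c(tsu = 0.75, suib = 0.45, core = 0.36, deep = 0.34, rem = 0.34))
}

# Gauss-Hermite nodes/weights by Golub-Welsch; returns nodes z and weights w
# such that E[f(Z)] ~ sum(w * f(z)) for Z ~ N(0,1)
gauss_hermite_normal <- function(n = 60) {
  i <- seq_len(n - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(i, i + 1)] <- sqrt(i / 2)
  Jm[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(Jm, symmetric = TRUE)
  w <- e$vectors[1, ]^2
  ord <- order(e$values)
  list(z = sqrt(2) * e$values[ord], w = w[ord])
}

#' Latent-normal parameters matching observed softplus moments
#'
#' Solves for the mean and SD of a Gaussian latent variable such that its
#' softplus image has the requested mean and SD (hours).
#'
#' @param mean_h,sd_h target observed mean and SD in hours.
#' @return c(mu, s) on the latent scale.
#' @export
anchor_latent <- function(mean_h, sd_h) {
  mean_h <- unname(mean_h); sd_h <- unname(sd_h)
  stopifnot(mean_h > 0, sd_h > 0)
  gh <- gauss_hermite_normal(60)
  obj <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    v <- softplus(mu + s * gh$z)
    m <- sum(gh$w * v)
    sdv <- sqrt(max(sum(gh$w * (v - m)^2), 1e-12))
    (m / mean_h - 1)^2 + (sdv / sd_h - 1)^2
  }
  init <- c(softplus_inv(mean_h), log(sd_h / max(stats::plogis(softplus_inv(mean_h)), 0.05)))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 1e-6) stop("anchor calibration failed for mean ", mean_h, " sd ", sd_h)
  c(mu = fit$par[1], s = exp(fit$par[2]))
}

.anchor_memo <- new.env(parent = emptyenv())

# latent anchors for every variable; the in-bed-use anchor is solved against
# the CAPPED margin (in-bed use is truncated at total use downstream), using
# 2-D Gauss-Hermite quadrature over the exact joint latent normal
latent_anchor_set <- function(config, sys) {
  vars <- config$vars
  mu <- s <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    a <- config$anchors[[v]]
    key <- sprintf("base_%.8g_%.8g", a["mean"], a["sd"])
    if (is.null(.anchor_memo[[key]])) .anchor_memo[[key]] <- anchor_latent(a["mean"], a["sd"])
    mu[v] <- .anchor_memo[[key]]["mu"]; s[v] <- .anchor_memo[[key]]["s"]
  }
  if (all(c("tsu", "suib") %in% vars)) {
    it <- match("tsu", vars); is <- match("suib", vars)
    rho <- sqrt((1 - config$icc["tsu"]) * (1 - config$icc["suib"])) * sys$Sigma[it, is]
    a <- config$anchors[["suib"]]
    key <- sprintf("cap_%.8g_%.8g_%.6g_%.6g_%.6g", a["mean"], a["sd"], rho, mu["tsu"], s["tsu"])
    if (is.null(.anchor_memo[[key]])) {
      gh <- gauss_hermite_normal(40)
      z1 <- rep(gh$z, each = 40); z2 <- rep(gh$z, 40)
      w <- rep(gh$w, each = 40) * rep(gh$w, 40)
      tsu_h <- softplus(mu["tsu"] + s["tsu"] * z1)
      zs <- rho * z1 + sqrt(1 - rho^2) * z2
      obj <- function(par) {
        v <- pmin(softplus(par[1] + exp(par[2]) * zs), tsu_h)
        m <- sum(w * v); sdv <- sqrt(max(sum(w * (v - m)^2), 1e-12))
        (m / a["mean"] - 1)^2 + (sdv / a["sd"] - 1)^2
      }
      fit <- stats::optim(c(mu["suib"], log(s["suib"])), obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-13))
      .anchor_memo[[key]] <- c(mu = unname(fit$par[1]), s = unname(exp(fit$par[2])))
    }
    mu["suib"] <- .anchor_memo[[key]]["mu"]; s["suib"] <- .anchor_memo[[key]]["s"]
  }
  list(mu = mu, s = s)
}

stationary_cov <- function(B, Q, tol = 1e-12, max_iter = 10000) {
  S <- Q
  for (i in seq_len(max_iter)) {
    S2 <- B %*% S %*% t(B) + Q
    if (max(abs(S2 - S)) < tol) return(S2)
    S <- S2
  }
  stop("stationary covariance iteration did not converge")
}

spectral_radius <- function(M) max(Mod(eigen(M, only.values = TRUE)$values))

# moment-matched standard-normal draws: exact column means 0 and exact
# identity sample covariance (classic Monte-Carlo variance reduction; a
# cohort of 68 then carries the population person-level structure rather
# than a noisy draw of it)
mm_norm <- function(n, k) {
  if (n <= k + 1) return(matrix(stats::rnorm(n * k), n, k))
  # stratified marginals: each column is a random permutation of the exact
  # standard-normal quantile grid, so nonlinear functionals of the draws
  # (the softplus observation map) also hit their population values
  q <- stats::qnorm((seq_len(n) - 0.5) / n)
  Z <- vapply(seq_len(k), function(j) q[sample.int(n)], numeric(n))
  Z <- sweep(Z, 2, colMeans(Z))
  Z %*% solve(chol(stats::cov(Z)))
}

# draw n x k innovations with exact sample covariance chol_target'chol_target,
# exactly orthogonal (in sample) to the columns of X: the population moment
# conditions E[e]=0, Cov(e)=target, Cov(e, X)=0 hold in every finite cohort
orth_norm <- function(n, k, X, chol_target) {
  if (n <= k + ncol(X) + 2) return(matrix(stats::rnorm(n * k), n, k) %*% chol_target)
  q <- stats::qnorm((seq_len(n) - 0.5) / n)
  Z <- vapply(seq_len(k), function(j) q[sample.int(n)], numeric(n))
  # project out the conditioning basis (QR handles near-collinear columns,
  # e.g. a variable and its softplus image)
  Q <- qr.Q(qr(cbind(1, X)))
  Z <- Z - Q %*% crossprod(Q, Z)
  (Z %*% solve(chol(stats::cov(Z)))) %*% chol_target
}

# residual SDs giving unit stationary variance for each latent variable
unit_resid_sd <- function(A, C) {
  k <- nrow(A)
  Minv <- solve(diag(k) - C)
  B <- Minv %*% A
  if (spectral_radius(B) >= 1) stop("non-stationary within dynamics (spectral radius >= 1)")
  d2 <- rep(1, k)
  for (i in 1:500) {
    Q <- Minv %*% diag(d2, k) %*% t(Minv)
    S <- stationary_cov(B, Q)
    if (max(abs(diag(S) - 1)) < 1e-10) break
    d2 <- pmax(d2 / diag(S), 1e-8)
  }
  list(d = sqrt(d2), B = B, Minv = Minv, Sigma = stationary_cov(B, Minv %*% diag(d2, k) %*% t(Minv)))
}

#' Configuration of the synthetic study generator
#'
#' Defaults reproduce the study design: 68 participants, 14 days, generating
#' coefficients equal to the printed standardized estimates of the fitted
#' model, and observed-scale anchors equal to the reported sample means/SDs.
#'
#' @param model 1 (total sleep) or 2 (sleep stages).
#' @param n_participants,n_days panel dimensions.
#' @param A,C lag-1 and contemporaneous coefficient matrices
#'   `[outcome, predictor]` on the observed standardized scale (defaults:
#'   the printed estimates). `C` must be strictly lower triangular in the
#'   causal order.
#' @param between_targets named vector of between-level stability targets.
#' @param icc named per-variable between/within variance ratios of the latent
#'   scale (starting values; [calibrate_between()] tunes them).
#' @param anchors named list of `c(mean, sd)` observed anchors in hours.
#' @param missing_sleep,missing_st day-level MCAR missingness probabilities
#'   for the sleep block and the screen-time block.
#' @param start_date first study date.
#' @param seed master seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(model = 1, n_participants = 68, n_days = 14,
                         A = NULL, C = NULL, between_targets = NULL, icc = NULL,
                         anchors = DEFAULT_ANCHORS,
                         missing_sleep = 0.05, missing_st = 0.05,
                         start_date = "2024-04-01", seed = 1) {
  def <- if (model == 1) model1_defaults() else model2_defaults()
  vars <- def$vars
  A <- A %||% def$A; C <- C %||% def$C
  between_targets <- between_targets %||% def$between
  icc <- icc %||% def$icc
  stopifnot(identical(dimnames(A), list(vars, vars)),
            identical(dimnames(C), list(vars, vars)))
  if (any(C[upper.tri(C, diag = TRUE)] != 0))
    stop("contemporaneous matrix C must be strictly lower triangular in the causal order")
  if (any(icc[vars] <= 0 | icc[vars] >= 1)) stop("icc must be in (0, 1)")
  for (v in vars) stopifnot(all(anchors[[v]] > 0))
  cfg <- structure(list(model = model, vars = vars,
                        n_participants = n_participants, n_days = n_days,
                        A = A, C = C, between_targets = between_targets,
                        icc = icc[vars], anchors = anchors,
                        missing_sleep = missing_sleep, missing_st = missing_st,
                        start_date = as.Date(start_date), seed = seed,
                        A_lat = NULL, C_lat = NULL, calibration = NULL),
                   class = "synth_config")
  # analytic first guess for the latent dynamics: observed-scale targets
  # inflated by the outcome's within/total SD ratio implied by the icc
  lat <- latent_guess(cfg)
  cfg$A_lat <- lat$A; cfg$C_lat <- lat$C
  unit_resid_sd(cfg$A_lat, cfg$C_lat)  # stationarity check at construction
  cfg
}

# within/total SD ratio of the observed series implied by icc at T days
# (person means absorb 1/T of the within variance); transform curvature is
# ignored here and corrected empirically by calibration
latent_guess <- function(cfg) {
  Tn <- cfg$n_days
  share_b <- cfg$icc + (1 - cfg$icc) / Tn
  r_y <- sqrt(pmax(1 - share_b, 0.05))
  A <- cfg$A / r_y[rownames(cfg$A)]   # divide each outcome row
  C <- cfg$C / r_y[rownames(cfg$C)]
  list(A = A, C = C)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synth_config: Model", x$model, "|", x$n_participants, "participants x",
      x$n_days, "days | seed", x$seed,
      if (!is.null(x$calibration)) "| calibrated" else "| uncalibrated", "\n")
  invisible(x)
}

#' Simulate a synthetic person-day panel
#'
#' Draws traits, iterates the within-level structural VAR day by day (solving
#' the contemporaneous paths in causal order), maps latents to duration
#' seconds via the anchored softplus transform, caps in-bed use at total use,
#' and applies day-level MCAR missingness last.
#'
#' @param config a [synth_config()].
#' @return list with `panel` (the person-day panel) and `truth` (all
#'   generating parameters, seeds, cap and missingness counts).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "panel"))
  vars <- config$vars
  k <- length(vars); N <- config$n_participants; Tn <- config$n_days
  sys <- unit_resid_sd(config$A_lat, config$C_lat)
  anc <- latent_anchor_set(config, sys)
  mu <- anc$mu; s_lat <- anc$s
  icc <- config$icc
  traits <- mm_norm(N, k); dimnames(traits) <- list(NULL, vars)
  ch_S <- chol(sys$Sigma)
  W <- array(NA_real_, c(N, Tn, k))
  w_prev <- orth_norm(N, k, traits, ch_S)   # stationary start
  W[, 1, ] <- w_prev
  # conditioning basis includes the observed-scale (softplus) image of the
  # previous day, so the moment conditions hold on the scale the model sees
  obs_of <- function(w) {
    o <- sapply(seq_len(k), function(j)
      softplus(mu[j] + s_lat[j] * (sqrt(icc[j]) * traits[, j] +
                                     sqrt(1 - icc[j]) * w[, j])))
    matrix(o, N, k)
  }
  for (t in 2:Tn) {
    e <- orth_norm(N, k, cbind(traits, w_prev, obs_of(w_prev)), diag(sys$d, k))
    wt <- t(sys$Minv %*% (config$A_lat %*% t(w_prev) + t(e)))
    W[, t, ] <- wt
    w_prev <- wt
  }
  hours <- array(NA_real_, c(N, Tn, k), dimnames = list(NULL, NULL, vars))
  for (j in seq_len(k)) {
    lat <- mu[j] + s_lat[j] * (sqrt(icc[j]) * traits[, j] +
                                 sqrt(1 - icc[j]) * W[, , j])
    hours[, , j] <- softplus(lat)
  }
  secs <- hours * 3600
  tsu <- secs[, , "tsu"]; suib_raw <- secs[, , "suib"]
  n_capped <- sum(suib_raw > tsu)
  suib <- pmin(suib_raw, tsu)
  if (config$model == 1) {
    sleep <- secs[, , "sleep"]; core <- deep <- rem <- matrix(NA_real_, N, Tn)
  } else {
    core <- secs[, , "core"]; deep <- secs[, , "deep"]; rem <- secs[, , "rem"]
    sleep <- core + deep + rem
  }
  miss_sleep <- matrix(stats::runif(N * Tn) < config$missing_sleep, N, Tn)
  miss_st <- matrix(stats::runif(N * Tn) < config$missing_st, N, Tn)
  sleep[miss_sleep] <- NA; core[miss_sleep] <- NA; deep[miss_sleep] <- NA; rem[miss_sleep] <- NA
  tsu[miss_st] <- NA; suib[miss_st] <- NA
  ids <- sprintf("synth%03d", seq_len(N))
  panel <- data.frame(
    participant_id = rep(ids, each = Tn),
    day_index = rep(seq_len(Tn), N),
    date = rep(config$start_date + seq_len(Tn) - 1L, N),
    tsu_s = as.vector(t(tsu)), suib_s = as.vector(t(suib)),
    sleep_total_s = as.vector(t(sleep)), rem_s = as.vector(t(rem)),
    core_s = as.vector(t(core)), deep_s = as.vector(t(deep)),
    stringsAsFactors = FALSE)
  truth <- list(A = config$A, C = config$C, A_lat = config$A_lat,
                C_lat = config$C_lat, icc = icc,
                between_targets = config$between_targets,
                resid_sd = sys$d, latent_mu = mu, latent_s = s_lat,
                seed = config$seed, n_capped = n_capped,
                cap_rate = n_capped / (N * Tn),
                cap_flag = n_capped / (N * Tn) >= 0.05,
                n_missing_sleep = sum(miss_sleep), n_missing_st = sum(miss_st))
  list(panel = panel, truth = truth)
}

# population fitted coefficients at large N: OLS per outcome on the
# standardized design (the probability limit of the Bayesian fit)
population_paths <- function(config, n_pop = 6000, seed = 1) {
  cfg <- config
  cfg$n_participants <- n_pop
  cfg$missing_sleep <- 0; cfg$missing_st <- 0
  cfg$seed <- seed
  sim <- simulate_panel(cfg)
  spec <- dsem_spec(config$model)
  dec <- decompose_panel(sim$panel, variables = spec$outcomes)
  des <- build_design(spec, dec)
  vars <- spec$outcomes
  bw <- matrix(NA_real_, length(vars), length(vars), dimnames = list(vars, vars))
  bb <- stats::setNames(rep(NA_real_, length(vars)), vars)
  for (o in vars) {
    d <- des[[o]]
    cf <- stats::lm.fit(cbind(1, d$Xw, d$Xb), d$y)$coefficients
    nv <- length(vars)
    bw[o, ] <- cf[1 + seq_len(nv)]
    bb[o] <- cf[1 + nv + which(vars == o)]
  }
  list(within = bw, between = bb)
}

#' Calibrate the generator to target standardized path values
#'
#' Tunes the per-variable between/within variance ratios so the population
#' between-level stability coefficients match their targets, and refines the
#' latent within-level coefficient matrices so the population fitted within
#' paths match the configured observed-scale targets (the softplus transform
#' attenuates correlations, materially so for short-duration variables).
#' Population quantities are measured by large-N simulation with common
#' random numbers across iterations.
#'
#' @param config a [synth_config()].
#' @param target_betas optional named vector of between-level stability
#'   targets (defaults to `config$between_targets`). Any target with absolute
#'   value >= 1 is infeasible and an error.
#' @param n_pop participants used for the population measurement.
#' @param max_iter,tol fixed-point iteration controls.
#' @param seed seed for the calibration simulations.
#' @return the calibrated `synth_config`, with a `calibration` element
#'   recording targets, achieved population values and convergence.
#' @export
calibrate_between <- function(config, target_betas = NULL, n_pop = 6000,
                              max_iter = 12, tol = 0.01, seed = 101) {
  stopifnot(inherits(config, "synth_config"))
  tb <- target_betas %||% config$between_targets
  if (any(abs(tb) >= 1)) stop("infeasible between-level target (|beta| >= 1)")
  config$between_targets <- tb
  vars <- config$vars
  achieved <- NULL
  for (it in seq_len(max_iter)) {
    pop <- population_paths(config, n_pop = n_pop, seed = derive_seed(seed, "calib"))
    # fitted within matrix [outcome, predictor] mixes timings per spec; the
    # targets live in A (lagged cells) and C (current cells)
    spec_t <- dsem_spec(config$model)$timing
    errA <- (config$A - pop$within) * (spec_t == "lagged")
    errC <- (config$C - pop$within) * (spec_t == "current")
    errB <- tb[vars] - pop$between[vars]
    achieved <- pop
    if (max(abs(errA), abs(errC), abs(errB)) < tol) break
    share_b <- config$icc + (1 - config$icc) / config$n_days
    r_y <- sqrt(pmax(1 - share_b, 0.05))
    step_A <- errA / r_y[rownames(errA)]
    step_C <- errC / r_y[rownames(errC)]
    A_new <- config$A_lat + 0.9 * step_A
    C_new <- config$C_lat + 0.9 * step_C
    # damped multiplicative update of the variance ratios on the share scale
    ratio <- pmin(pmax((tb[vars] / pmax(pop$between[vars], 1e-3))^1.5, 0.5), 2)
    icc_new <- pmin(pmax(config$icc * ratio, 1e-3), 0.985)
    ok <- tryCatch({ unit_resid_sd(A_new, C_new); TRUE }, error = function(e) FALSE)
    if (!ok) { A_new <- (A_new + config$A_lat) / 2; C_new <- (C_new + config$C_lat) / 2 }
    config$A_lat <- A_new; config$C_lat <- C_new; config$icc <- icc_new
  }
  config$calibration <- list(
    between_targets = tb, achieved_between = achieved$between,
    within_targets_lag = config$A, within_targets_cur = config$C,
    achieved_within = achieved$within, n_pop = n_pop, iterations = it,
    converged = max(abs(tb[vars] - achieved$between[vars])) < max(tol, 0.015),
    # a target below the feasible floor shows as a pinned-low variance ratio
    # that still overshoots the target: overlapping person means of the same
    # series keep a positive association even with no trait variance
    feasible_floor_hit = any(config$icc <= 2e-3 |
                               (achieved$between[vars] - tb[vars] > max(3 * tol, 0.03) &
                                  config$icc < 0.05)))
  config
}
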