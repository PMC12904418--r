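complete_sim <- function(n = 20, seed = 50, model = 1) {
  cfg <- synth_config(model = model, n_participants = n,
                      missing_sleep = 0, missing_st = 0, seed = seed)
  simulate_panel(cfg)$panel
}

small_fit <- function(panel, model = 1, iter = 600, seed = 60) {
  dsem_fit(panel, dsem_spec(model, iter = iter), seed = seed)
}

test_that("design follows the timing rule per outcome", {
  spec <- dsem_spec(1)
  d <- build_design(spec, decompose_panel(complete_sim(10)))
  # sleep outcome: own lag + both use paths current
  expect_equal(d$sleep$labels$timing,
               unname(c(tsu = "current", suib = "current",
                        sleep = "lagged")[d$sleep$labels$predictor]))
  # total-use outcome: everything lagged
  expect_true(all(d$tsu$labels$timing == "lagged"))
  # in-bed-use outcome: total use current, rest lagged
  expect_equal(d$suib$labels$timing[d$suib$labels$predictor == "tsu"], "current")
  expect_equal(d$suib$labels$timing[d$suib$labels$predictor == "suib"], "lagged")
  # 13 design rows per participant, 3 within + 3 between columns
  expect_equal(length(d$sleep$y), 10 * 13)
  expect_equal(ncol(d$sleep$Xw), 3); expect_equal(ncol(d$sleep$Xb), 3)
  # standardized columns have unit scale
  expect_equal(sd(d$sleep$y), 1, tolerance = 1e-9)
  expect_equal(apply(d$sleep$Xw, 2, sd), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a model variable absent from the panel is an error", {
  dec <- decompose_panel(complete_sim(6), variables = c("tsu", "suib"))
  expect_error(build_design(dsem_spec(1), dec), "lacks model variable")
})

test_that("the significance rule equals direct percentile computation", {
  expect_true(significance(rep(0.5, 2000)))
  set.seed(1); expect_false(significance(rnorm(4000)))
  expect_true(significance(runif(2000, 0.01, 0.02)))
  set.seed(2)
  for (rep in 1:50) {
    draws <- rnorm(2000, mean = runif(1, -.2, .2), sd = runif(1, .01, .2))
    q <- quantile(draws, c(.025, .975))
    expect_identical(significance(draws), unname(q[1] > 0 | q[2] < 0))
  }
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(3)
  iid <- cbind(rnorm(4000), rnorm(4000))
  expect_lt(abs(rhat(iid) - 1), 0.005)
  apart <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(rhat(apart), 1.5)
  expect_true(is.nan(rhat(cbind(rep(1, 100), rnorm(100)))))
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), ">= 2 chains")
})

test_that("variance inflation factors match closed forms", {
  set.seed(4)
  raw <- qr.Q(qr(scale(matrix(rnorm(200), 100, 2), scale = FALSE)))
  u1 <- raw[, 1]; u2 <- raw[, 2]
  X_orth <- cbind(a = u1, b = u2)
  expect_equal(as.numeric(vif(X_orth)), c(1, 1), tolerance = 1e-9)
  # exact sample correlation 0.6 -> VIF = 1/(1-0.36)
  X_cor <- cbind(a = u1, b = 0.6 * u1 + 0.8 * u2)
  expect_equal(as.numeric(vif(X_cor)), c(1.5625, 1.5625), tolerance = 1e-9)
  X_dup <- cbind(a = u1, b = u1)
  v <- vif(X_dup)
  expect_true(all(attr(v, "flagged")))
  expect_true(all(v > 1e6))
})

test_that("single-level reduction matches the conjugate ridge estimate", {
  set.seed(5)
  X <- matrix(rnorm(120), 60, 2)
  y <- X %*% c(0.8, -0.4) + rnorm(60)
  run <- gibbs_lmm(y, X, person = rep("p1", 60), iter = 4000, seed = 6,
                   random_intercept = FALSE)
  s2 <- mean(run$sigma^2)
  Xi <- cbind(1, X)
  ridge <- solve(crossprod(Xi) + diag(s2 / 100, 3), crossprod(Xi, y))
  expect_equal(unname(colMeans(run$beta)), as.numeric(ridge), tolerance = 0.02)
})

test_that("pooled estimates are invariant to imputation order", {
  cfg <- synth_config(n_participants = 12, seed = 51)
  panel <- simulate_panel(cfg)$panel
  imp <- impute_panel(panel, variables = c("tsu", "suib", "sleep"), m = 3, seed = 7)
  rev_imp <- imp
  rev_imp$panels <- rev(imp$panels)
  f1 <- dsem_fit(imp, dsem_spec(1, iter = 400), seed = 8)
  f2 <- dsem_fit(rev_imp, dsem_spec(1, iter = 400), seed = 8)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-12)
})

test_that("a single complete imputation equals fitting the panel directly", {
  panel <- complete_sim(10, seed = 52)
  imp <- impute_panel(panel, variables = c("tsu", "suib", "sleep"), m = 1, seed = 1)
  f_imp <- dsem_fit(imp, dsem_spec(1, iter = 400), seed = 9)
  f_dir <- dsem_fit(panel, dsem_spec(1, iter = 400), seed = 9)
  expect_equal(f_imp$estimates, f_dir$estimates, tolerance = 1e-12)
})

test_that("null data produce small, mostly non-significant within paths", {
  zero <- matrix(0, 3, 3, dimnames = list(c("tsu", "suib", "sleep"),
                                          c("tsu", "suib", "sleep")))
  sig <- 0L; total <- 0L; betas <- c()
  for (s in 1:8) {
    cfg <- synth_config(model = 1, n_participants = 40, A = zero, C = zero,
                        missing_sleep = 0, missing_st = 0, seed = 300 + s)
    fit <- small_fit(simulate_panel(cfg)$panel, iter = 500, seed = 70 + s)
    w <- fit$estimates[fit$estimates$level == "within", ]
    sig <- sig + sum(w$significant); total <- total + nrow(w)
    betas <- c(betas, w$beta)
  }
  expect_lt(sig / total, 0.15)
  expect_lt(max(abs(betas)), 0.15)
})

test_that("posterior predictive p-values react to shifted observations", {
  fit <- small_fit(complete_sim(16, seed = 53), iter = 600, seed = 61)
  p <- ppc_mean(fit, seed = 1)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(p > 0.05 & p < 0.95))   # well-specified model, typical means
  shift <- fit
  for (o in names(shift$designs[[1]]))
    shift$designs[[1]][[o]]$y <- shift$designs[[1]][[o]]$y + 10
  expect_true(all(ppc_mean(shift, seed = 1) == 0))
  shift_dn <- fit
  for (o in names(shift_dn$designs[[1]]))
    shift_dn$designs[[1]][[o]]$y <- shift_dn$designs[[1]][[o]]$y - 10
  expect_true(all(ppc_mean(shift_dn, seed = 1) == 1))
})

test_that("LOO comparison is zero against itself and errors on mismatched sets", {
  fit <- small_fit(complete_sim(12, seed = 54), iter = 500, seed = 62)
  cmp <- loo_compare(fit, fit)
  expect_equal(cmp$elpd_diff, 0)
  expect_equal(cmp$se_diff, 0)
  other <- small_fit(complete_sim(11, seed = 55), iter = 500, seed = 63)
  expect_error(loo_compare(fit, other), "same observation set")
})

test_that("LOO favours the true model over one fit to scrambled outcomes", {
  for (s in 1:2) {
    panel <- complete_sim(30, seed = 56 + s)
    scram <- panel
    set.seed(90 + s)
    for (pid in unique(scram$participant_id)) {
      rows <- which(scram$participant_id == pid)
      scram$sleep_total_s[rows] <- scram$sleep_total_s[sample(rows)]
    }
    fit_true <- small_fit(panel, iter = 500, seed = 64)
    fit_scram <- small_fit(scram, iter = 500, seed = 65)
    # compare on the common observation grid: scrambling preserves ids
    cmp <- loo_compare(fit_true, fit_scram)
    expect_gt(cmp$elpd_diff, 0)
  }
})
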