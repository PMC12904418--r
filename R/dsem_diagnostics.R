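# Model diagnostics: variance inflation factors on the within-level design,
# posterior predictive checks on outcome means, and PSIS-LOO model comparison.

#' Variance inflation factors
#'
#' VIF of each design column regressed on the others, `1/(1 - R^2)`. Values
#' above 1e6 (numerically collinear columns) are flagged.
#'
#' @param X design matrix with >= 2 columns.
#' @return named numeric vector with attribute `"flagged"` (logical).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("vif needs >= 2 columns")
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  attr(out, "flagged") <- !is.finite(out) | out > 1e6
  out
}

#' Within-level VIFs for every outcome of a fit
#' @param fit a [dsem_fit()] result.
#' @return named list of [vif()] vectors (pooled within-level rows, first
#'   imputation's design).
#' @export
vif_within <- function(fit) {
  lapply(fit$designs[[1]], function(d) vif(d$Xw))
}

# draw indices of the thinned person-intercept draws within the kept draws
alpha_draw_index <- function(n_kept, thin = 5L) seq(1L, n_kept, by = thin)

#' Posterior predictive check on outcome means
#'
#' For each outcome, datasets are replicated from the posterior predictive
#' distribution (thinned draws across chains and imputations) and the
#' proportion of replicates whose mean exceeds the observed mean is reported.
#' Values near 0.5 indicate the observed mean is typical under the model.
#'
#' @param fit a [dsem_fit()] result.
#' @param seed seed for the replication noise.
#' @return named numeric vector of posterior predictive p-values.
#' @export
ppc_mean <- function(fit, seed = 1) {
  set.seed(derive_seed(seed, "ppc"))
  out <- stats::setNames(numeric(length(fit$spec$outcomes)), fit$spec$outcomes)
  for (o in fit$spec$outcomes) {
    exceed <- 0L; total <- 0L
    for (mi in seq_along(fit$runs)) {
      d <- fit$designs[[mi]][[o]]
      X <- cbind(1, d$Xw, d$Xb)
      pidx <- as.integer(d$person)
      obs_mean <- mean(d$y)
      for (run in fit$runs[[mi]][[o]]) {
        ks <- alpha_draw_index(nrow(run$beta))
        for (ai in seq_along(ks)) {
          s <- ks[ai]
          mu <- as.numeric(X %*% run$beta[s, ]) + run$alpha[ai, pidx]
          yrep <- mu + stats::rnorm(length(mu), 0, run$sigma[s])
          exceed <- exceed + (mean(yrep) > obs_mean)
          total <- total + 1L
        }
      }
    }
    out[o] <- exceed / total
  }
  out
}

# ---- PSIS-LOO ---------------------------------------------------------------

# generalized Pareto fit to exceedances: profile-likelihood point estimate
# with the standard grid over the reparameterized scale (theta). k is the
# tail shape (positive = heavy tail), sigma the scale.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  k_of <- function(th) mean(log1p(-th * x))
  lik <- vapply(theta, function(th) {
    k <- k_of(th)
    if (!is.finite(k) || k == 0 || th == 0) return(-Inf)
    n * (log(-th / k) - k - 1)
  }, numeric(1))
  w <- exp(lik - max(lik)); w <- w / sum(w)
  th_hat <- sum(theta * w)
  k_hat <- k_of(th_hat)
  list(k = k_hat, sigma = -k_hat / th_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * expm1(-k * log1p(-p)) / k
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# Pareto-smoothed importance weights from log ratios; returns smoothed log
# weights (unnormalized) and the tail shape k-hat
psis_weights <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) return(list(lw = lr, khat = NA_real_))
  ord <- order(lr)
  tail_ids <- ord[(S - M + 1):S]
  cut <- exp(lr[ord[S - M]])
  exceed <- exp(lr[tail_ids]) - cut
  if (all(exceed <= 0) || stats::sd(exceed) == 0) return(list(lw = lr, khat = NA_real_))
  fitp <- gpd_fit(exceed[exceed > 0])
  qq <- qgpd((seq_len(M) - 0.5) / M, fitp$k, fitp$sigma)
  lr[tail_ids[order(lr[tail_ids])]] <- log(cut + qq)
  # truncate at S^(3/4) * mean weight
  lw <- lr - logsumexp(lr)
  lw <- pmin(lw, 0.75 * log(S) - log(S))
  list(lw = lw, khat = fitp$k)
}

#' Pointwise PSIS-LOO expected log predictive density
#'
#' Computes leave-one-out pointwise elpd per observation (participant-day),
#' summed across the fit's outcomes and averaged across imputations. Smoothing
#' follows the Pareto-smoothed importance sampling recipe (generalized Pareto
#' fit to the top ~20% of importance ratios, truncated).
#'
#' @param fit a [dsem_fit()] result.
#' @return list with `elpd`, `se`, `pointwise` (named by `participant:day`),
#'   and the worst Pareto `khat` seen.
#' @export
loo_elpd <- function(fit) {
  ids <- paste(fit$designs[[1]][[1]]$person, fit$designs[[1]][[1]]$day_index, sep = ":")
  pw_sum <- stats::setNames(rep(0, length(ids)), ids)
  worst_k <- -Inf
  for (o in fit$spec$outcomes) {
    per_imp <- matrix(0, length(ids), length(fit$runs))
    for (mi in seq_along(fit$runs)) {
      d <- fit$designs[[mi]][[o]]
      X <- cbind(1, d$Xw, d$Xb)
      pidx <- as.integer(d$person)
      ll <- NULL
      for (run in fit$runs[[mi]][[o]]) {
        ks <- alpha_draw_index(nrow(run$beta))
        mu <- X %*% t(run$beta[ks, , drop = FALSE]) + t(run$alpha[, pidx, drop = FALSE])
        li <- matrix(stats::dnorm(d$y, mu, rep(run$sigma[ks], each = length(d$y)), log = TRUE),
                     nrow = length(d$y))
        ll <- cbind(ll, li)   # n x S
      }
      for (i in seq_along(ids)) {
        ps <- psis_weights(-ll[i, ])
        if (!is.na(ps$khat)) worst_k <- max(worst_k, ps$khat)
        per_imp[i, mi] <- logsumexp(ps$lw + ll[i, ]) - logsumexp(ps$lw)
      }
    }
    pw_sum <- pw_sum + rowMeans(per_imp)
  }
  list(elpd = sum(pw_sum), se = stats::sd(pw_sum) * sqrt(length(pw_sum)),
       pointwise = pw_sum, khat = worst_k)
}

#' Compare two fits by PSIS-LOO
#'
#' @param fit_a,fit_b [dsem_fit()] results on the same observation set
#'   (identical participant-day ids); mismatched sets are an error.
#' @return list with `elpd_diff` (negative means `fit_a` predicts worse),
#'   `se_diff`, and each fit's `elpd`/`se`.
#' @export
loo_compare <- function(fit_a, fit_b) {
  la <- loo_elpd(fit_a); lb <- loo_elpd(fit_b)
  if (!identical(sort(names(la$pointwise)), sort(names(lb$pointwise))))
    stop("fits are not on the same observation set")
  pb <- lb$pointwise[names(la$pointwise)]
  d <- la$pointwise - pb
  list(elpd_diff = sum(d), se_diff = stats::sd(d) * sqrt(length(d)),
       elpd_a = la$elpd, se_a = la$se, elpd_b = lb$elpd, se_b = lb$se)
}
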