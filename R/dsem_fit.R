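# Bayesian estimation of the two-level model by Gibbs sampling.
#
# Each outcome regression is a Gaussian linear mixed model
#   y_it = x_it' beta + alpha_i + e_it,  alpha_i ~ N(0, tau^2),  e ~ N(0, s^2)
# with x_it the standardized within- and between-level design columns plus an
# intercept. Priors: beta ~ N(0, beta_sd^2); the residual and random-intercept
# SDs carry half-Student-t(df, 0, scale) priors via the inverse-gamma scale
# mixture (sigma^2 | a ~ IG(df/2, df/a), a ~ IG(1/2, 1/scale^2)), which keeps
# every conditional conjugate. Imputations are pooled by concatenating
# post-warmup draws.

#' Gibbs sampler for one outcome regression
#'
#' @param y standardized outcome vector.
#' @param X design matrix (within + between columns; an intercept is added).
#' @param person factor assigning rows to participants.
#' @param prior list with `beta_sd`, `scale_df`, `scale`.
#' @param iter total iterations; the first `warmup` are discarded.
#' @param warmup warmup iterations.
#' @param seed integer seed for this chain.
#' @param random_intercept set `FALSE` to drop the person-level intercepts
#'   (used for single-participant reductions).
#' @param alpha_thin keep every `alpha_thin`-th draw of the person intercepts.
#' @return list with `beta` (draws x coef matrix, intercept column `"(icpt)"`),
#'   `sigma`, `tau` (vectors), `alpha` (thinned draws x persons matrix).
#' @export
gibbs_lmm <- function(y, X, person, prior = list(beta_sd = 10, scale_df = 3, scale = 2.5),
                      iter = 5000, warmup = floor(iter / 2), seed = 1,
                      random_intercept = TRUE, alpha_thin = 5L) {
  set.seed(seed)
  y <- as.numeric(y)
  X <- cbind(`(icpt)` = 1, X)
  n <- length(y); p <- ncol(X)
  person <- droplevels(as.factor(person))
  J <- nlevels(person); pidx <- as.integer(person)
  nj <- tabulate(pidx, J)
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  XtZ <- t(rowsum(X, pidx))              # p x J
  nu <- prior$scale_df; A2 <- prior$scale^2
  prior_prec <- diag(1 / prior$beta_sd^2, p)
  beta <- rep(0, p); alpha <- rep(0, J)
  sig2 <- stats::var(y); tau2 <- max(stats::var(y) / 4, 1e-4)
  a_sig <- 1; a_tau <- 1
  keep <- iter - warmup
  out_beta <- matrix(NA_real_, keep, p, dimnames = list(NULL, colnames(X)))
  out_sig <- numeric(keep); out_tau <- numeric(keep)
  out_alpha <- matrix(NA_real_, ceiling(keep / alpha_thin), J)
  ai <- 0L
  rinvgamma <- function(shape, rate) 1 / stats::rgamma(1, shape = shape, rate = rate)
  for (s in seq_len(iter)) {
    # beta | .
    resid_target <- Xty - XtZ %*% alpha[seq_len(J)]
    Q <- XtX / sig2 + prior_prec
    ch <- chol(Q)
    mu <- backsolve(ch, forwardsolve(t(ch), resid_target / sig2))
    beta <- mu + backsolve(ch, stats::rnorm(p))
    r <- y - as.numeric(X %*% beta)
    if (random_intercept) {
      sj <- rowsum(r, pidx)[, 1]
      vj <- 1 / (nj / sig2 + 1 / tau2)
      alpha <- stats::rnorm(J, vj * sj / sig2, sqrt(vj))
      # tau2 | alpha (half-t via scale mixture)
      tau2 <- rinvgamma((nu + J) / 2, nu / a_tau + sum(alpha^2) / 2)
      a_tau <- rinvgamma((nu + 1) / 2, nu / tau2 + 1 / A2)
    }
    e <- r - alpha[pidx]
    sig2 <- rinvgamma((nu + n) / 2, nu / a_sig + sum(e^2) / 2)
    a_sig <- rinvgamma((nu + 1) / 2, nu / sig2 + 1 / A2)
    if (s > warmup) {
      k <- s - warmup
      out_beta[k, ] <- beta
      out_sig[k] <- sqrt(sig2); out_tau[k] <- sqrt(tau2)
      if (k %% alpha_thin == 1L || alpha_thin == 1L) {
        ai <- ai + 1L
        out_alpha[ai, ] <- alpha
      }
    }
  }
  list(beta = out_beta, sigma = out_sig, tau = out_tau,
       alpha = out_alpha[seq_len(ai), , drop = FALSE],
       persons = levels(person))
}

#' Credible-interval significance rule
#'
#' A path is significant when the empirical central 95% interval of its
#' posterior draws excludes zero.
#'
#' @param draws numeric vector of posterior draws (>= 1000 recommended).
#' @param level credible level.
#' @return logical scalar.
#' @export
significance <- function(draws, level = 0.95) {
  q <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  q[1] > 0 || q[2] < 0
}

#' Rank-normalized split R-hat
#'
#' Splits each chain in half, rank-normalizes the pooled draws, and computes
#' the classic potential-scale-reduction factor on the normalized values.
#' Returns `NaN` when any split chain is constant.
#'
#' @param chains draws x chains matrix (>= 2 chains).
#' @return scalar R-hat.
#' @export
rhat <- function(chains) {
  chains <- as.matrix(chains)
  if (ncol(chains) < 2) stop("rhat needs >= 2 chains")
  S <- nrow(chains); half <- floor(S / 2)
  split <- cbind(chains[seq_len(half), , drop = FALSE],
                 chains[(S - half + 1):S, , drop = FALSE])
  if (any(apply(split, 2, stats::sd) == 0)) return(NaN)
  z <- matrix(stats::qnorm((rank(split) - 3 / 8) / (length(split) + 1 / 4)),
              nrow = nrow(split))
  m <- ncol(z); nn <- nrow(z)
  means <- colMeans(z); vars <- apply(z, 2, stats::var)
  B <- nn * stats::var(means); W <- mean(vars)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Fit a two-level dynamic structural equation model
#'
#' Fits every outcome regression of `spec` to each completed panel of an
#' imputation set (or a single panel), running `spec$chains` chains per
#' imputation, and pools posterior draws by concatenation across chains and
#' imputations. Standardized path estimates, 95% credible intervals, the
#' significance flag and the (worst-case across imputations) split R-hat are
#' tabulated per path. Non-convergence (R-hat >= 1.01 on a structural
#' coefficient) is flagged in the result, never thrown.
#'
#' @param data an `imputation_set`, or a panel data.frame (treated as a single
#'   complete imputation).
#' @param spec a [dsem_spec()].
#' @param seed master seed; chain and imputation seeds are derived from it.
#' @param random_intercept passed to [gibbs_lmm()].
#' @return object of class `dsem_fit` with elements `estimates` (the path
#'   table), `draws` (pooled draws per outcome), `runs` (per-imputation
#'   per-chain draws), `designs` (per-imputation design lists), `spec`,
#'   `converged`, `seed`.
#' @export
dsem_fit <- function(data, spec, seed = 1, random_intercept = TRUE) {
  panels <- if (inherits(data, "imputation_set")) data$panels else list(data)
  designs <- lapply(panels, function(p)
    build_design(spec, decompose_panel(p, variables = spec$outcomes)))
  # chain seeds derive from the completed data content, not the imputation
  # index, so pooled results are invariant to imputation order
  ptags <- vapply(panels, function(p) hash_id(paste(
    sprintf("%.6g", unlist(p[intersect(unname(VAR_COLS), names(p))], use.names = FALSE)),
    collapse = ","), "imp-tag"), character(1))
  runs <- list()    # runs[[imp]][[outcome]][[chain]]
  for (mi in seq_along(designs)) {
    runs[[mi]] <- list()
    for (o in spec$outcomes) {
      d <- designs[[mi]][[o]]
      X <- cbind(d$Xw, d$Xb)
      runs[[mi]][[o]] <- lapply(seq_len(spec$chains), function(ch)
        gibbs_lmm(d$y, X, d$person, prior = spec$prior, iter = spec$iter,
                  warmup = spec$warmup,
                  seed = derive_seed(seed, sprintf("fit-%s-%s-c%d", ptags[mi], o, ch)),
                  random_intercept = random_intercept))
    }
  }
  # pool draws and tabulate path estimates
  est <- list(); pooled <- list()
  for (o in spec$outcomes) {
    labels <- designs[[1]][[o]]$labels
    beta_all <- do.call(rbind, lapply(runs, function(rm)
      do.call(rbind, lapply(rm[[o]], `[[`, "beta"))))
    pooled[[o]] <- beta_all
    nv <- nrow(labels)
    for (level in c("within", "between")) {
      cols <- 1L + (if (level == "within") seq_len(nv) else nv + seq_len(nv))
      for (j in seq_len(nv)) {
        dr <- beta_all[, cols[j]]
        rh <- max(vapply(runs, function(rm)
          rhat(sapply(rm[[o]], function(run) run$beta[, cols[j]])), numeric(1)))
        q <- stats::quantile(dr, c(.025, .975), names = FALSE)
        est[[length(est) + 1L]] <- data.frame(
          outcome = o, predictor = labels$predictor[j], timing = labels$timing[j],
          level = level, beta = mean(dr), ci_low = q[1], ci_high = q[2],
          significant = significance(dr), rhat = rh, stringsAsFactors = FALSE)
      }
    }
  }
  estimates <- do.call(rbind, est)
  structure(list(estimates = estimates, draws = pooled, runs = runs,
                 designs = designs, spec = spec, seed = seed,
                 converged = all(estimates$rhat < 1.01, na.rm = TRUE)),
            class = "dsem_fit")
}

#' @export
print.dsem_fit <- function(x, digits = 2, ...) {
  cat("Two-level DSEM fit (Model", x$spec$model, "),",
      length(x$runs), "imputation(s) x", x$spec$chains, "chains x",
      x$spec$iter, "iterations\n")
  cat("converged:", x$converged, "(max R-hat", round(max(x$estimates$rhat), 3), ")\n\n")
  tab <- x$estimates
  tab$beta <- round(tab$beta, digits)
  tab$ci <- sprintf("[%.*f; %.*f]", digits, tab$ci_low, digits, tab$ci_high)
  tab$sig <- ifelse(tab$significant, "*", "")
  print(tab[c("outcome", "predictor", "timing", "level", "beta", "ci", "sig")],
        row.names = FALSE)
  invisible(x)
}

#' Extract one path estimate from a fit
#'
#' @param fit a [dsem_fit()] result.
#' @param outcome,predictor short variable names.
#' @param level `"within"` or `"between"`.
#' @return one-row data.frame from the estimates table.
#' @export
path_estimate <- function(fit, outcome, predictor, level = "within") {
  e <- fit$estimates
  row <- e[e$outcome == outcome & e$predictor == predictor & e$level == level, ]
  if (nrow(row) != 1) stop("path not found: ", predictor, " -> ", outcome, " (", level, ")")
  row
}
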