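# Causal-effect estimators on harmonized instrument sets.
#
# Every estimator consumes a `harmonized_pairs` data.frame (per-SNP
# exposure/outcome effects aligned to a shared effect allele) and returns
# an `mr_estimate`: the log-scale causal effect with SE, 95% CI, p-value
# and the odds-ratio transform.

new_mr_estimate <- function(method, beta, se, pval, n_snps, extra = list()) {
  est <- list(
    method = method, beta = beta, se = se,
    ci_low = beta - stats::qnorm(0.975) * se,
    ci_high = beta + stats::qnorm(0.975) * se,
    pval = pval, n_snps = n_snps, extra = extra
  )
  est$or <- exp(est$beta)
  est$or_low <- exp(est$ci_low)
  est$or_high <- exp(est$ci_high)
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "MR estimate [%s, %d SNP%s]\n  beta = %.4f (SE %.4f), p = %.3g\n  OR = %.2f (95%% CI %.2f-%.2f)\n",
    x$method, x$n_snps, if (x$n_snps == 1) "" else "s",
    x$beta, x$se, x$pval, x$or, x$or_low, x$or_high
  ))
  invisible(x)
}

check_pairs <- function(pairs, min_snps, method) {
  if (nrow(pairs) < min_snps) {
    stop_mrkit(sprintf("%s requires at least %d SNPs, got %d",
                       method, min_snps, nrow(pairs)),
               "mrkit_insufficient_instruments")
  }
  zero <- pairs$SNP[pairs$beta_exp == 0]
  if (length(zero) > 0) {
    stop_mrkit(paste0("degenerate instrument (exposure beta = 0): ",
                      paste(zero, collapse = ", ")),
               "mrkit_degenerate_instrument")
  }
  invisible(pairs)
}

#' Wald ratio estimator
#'
#' Single-SNP causal estimate: the outcome effect divided by the exposure
#' effect.  The default SE is the first-order approximation
#' `se_out / |beta_exp|`; `se_method = "second"` adds the delta-method
#' term for uncertainty in the exposure effect,
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`.
#'
#' @param pair one-row `harmonized_pairs` data.frame.
#' @param se_method `"first"` (default) or `"second"`.
#' @return an `mr_estimate`.
#' @export
wald_ratio <- function(pair, se_method = c("first", "second")) {
  se_method <- match.arg(se_method)
  check_pairs(pair, 1, "wald_ratio")
  pair <- pair[1, ]
  beta <- pair$beta_out / pair$beta_exp
  se <- if (se_method == "first") {
    pair$se_out / abs(pair$beta_exp)
  } else {
    sqrt(pair$se_out^2 / pair$beta_exp^2 +
           pair$beta_out^2 * pair$se_exp^2 / pair$beta_exp^4)
  }
  new_mr_estimate("wald_ratio", beta, se, pval_norm(beta, se), 1L)
}

ivw_weights <- function(pairs) pairs$beta_exp^2 / pairs$se_out^2

#' Inverse-variance-weighted (IVW) estimator
#'
#' Inverse-variance-weighted average of the per-SNP Wald ratios, with
#' first-order weights `w_j = beta_exp_j^2 / se_out_j^2`; equivalent to a
#' weighted regression of outcome on exposure effects through the origin.
#' The default multiplicative-random-effects mode inflates the
#' fixed-effect SE by `max(1, sqrt(Q / (J - 1)))` — fixed-effect behavior
#' when the instruments are under-dispersed.  A single SNP delegates to
#' [wald_ratio()].
#'
#' @param pairs `harmonized_pairs` data.frame.
#' @param mode `"mre"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return an `mr_estimate`; `extra` carries Cochran's `Q` and the mode.
#' @export
ivw <- function(pairs, mode = c("mre", "fixed")) {
  mode <- match.arg(mode)
  check_pairs(pairs, 1, "ivw")
  if (nrow(pairs) == 1) return(wald_ratio(pairs))
  J <- nrow(pairs)
  w <- ivw_weights(pairs)
  ratio <- pairs$beta_out / pairs$beta_exp
  beta <- sum(w * ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  Q <- sum(w * (ratio - beta)^2)
  se <- if (mode == "mre") se_fixed * max(1, sqrt(Q / (J - 1))) else se_fixed
  new_mr_estimate("ivw", beta, se, pval_norm(beta, se), J,
                  extra = list(Q = Q, mode = mode))
}

# Weighted least squares of y on design X; returns coefficients, their
# SEs with the residual variance factor floored at 1, sigma2 and RSS.
wls_floored <- function(X, y, w, df) {
  XtW <- t(X * w)
  XtWX_inv <- solve(XtW %*% X)
  coefs <- unname(drop(XtWX_inv %*% (XtW %*% y)))
  resid <- y - drop(X %*% coefs)
  rss <- sum(w * resid^2)
  sigma2 <- max(1, rss / df)
  list(coef = coefs, se = unname(sqrt(sigma2 * diag(XtWX_inv))),
       sigma2 = sigma2, rss = rss)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with
#' a free intercept (weights `1 / se_out^2`), after orienting every SNP so
#' the exposure effect is non-negative.  The slope is the causal estimate,
#' consistent under the InSIDE assumption even when all instruments are
#' pleiotropic; a nonzero intercept indicates directional pleiotropy.
#' SEs use the weighted-regression residual variance floored at 1;
#' p-values are from the t distribution with `J - 2` df.
#'
#' @param pairs `harmonized_pairs` data.frame with at least 3 SNPs.
#' @return an `mr_estimate` for the slope; `extra` carries the intercept,
#'   its SE and p-value, and the residual variance factor.
#' @export
mr_egger <- function(pairs) {
  check_pairs(pairs, 3, "mr_egger")
  J <- nrow(pairs)
  flip <- pairs$beta_exp < 0
  x <- abs(pairs$beta_exp)
  y <- ifelse(flip, -pairs$beta_out, pairs$beta_out)
  if (stats::sd(x) < 1e-12 * max(abs(x))) {
    stop_mrkit("exposure effects are collinear after orientation",
               "mrkit_collinear_design")
  }
  w <- 1 / pairs$se_out^2
  fit <- wls_floored(cbind(1, x), y, w, df = J - 2)
  slope <- fit$coef[2]; slope_se <- fit$se[2]
  int <- fit$coef[1]; int_se <- fit$se[1]
  pt2 <- function(est, se) 2 * stats::pt(-abs(est / se), df = J - 2)
  new_mr_estimate("egger", slope, slope_se, pt2(slope, slope_se), J,
                  extra = list(intercept = int, intercept_se = int_se,
                               intercept_pval = pt2(int, int_se),
                               sigma2 = fit$sigma2))
}

# Weighted-median point estimate: sort ratio estimates, normalize weights,
# interpolate the cumulative midpoint weights at 0.5.
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  b <- ratio[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  J <- length(b)
  if (0.5 >= s[J]) return(b[J])
  k <- max(which(s < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted-median estimator
#'
#' The inverse-variance-weighted median of the per-SNP Wald ratios:
#' consistent as long as instruments carrying at least half the weight are
#' valid.  The SE comes from a parametric bootstrap that resamples the
#' exposure and outcome effects from normal distributions with their
#' reported SEs and recomputes the weighted median.
#'
#' @param pairs `harmonized_pairs` data.frame with at least 3 SNPs.
#' @param n_boot bootstrap replicates (at least 100; default 1,000).
#' @param seed integer seed for the bootstrap (required: results are
#'   reproducible bit-for-bit under a fixed seed).
#' @return an `mr_estimate`.
#' @export
weighted_median <- function(pairs, n_boot = 1000, seed) {
  check_pairs(pairs, 3, "weighted_median")
  if (missing(seed)) {
    stop_mrkit("weighted_median requires an explicit seed", "mrkit_config_error")
  }
  if (n_boot < 100) {
    stop_mrkit("n_boot must be at least 100", "mrkit_config_error")
  }
  J <- nrow(pairs)
  ratio <- pairs$beta_out / pairs$beta_exp
  beta <- weighted_median_point(ratio, ivw_weights(pairs))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(J, pairs$beta_exp, pairs$se_exp)
      by <- stats::rnorm(J, pairs$beta_out, pairs$se_out)
      weighted_median_point(by / bx, bx^2 / pairs$se_out^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  new_mr_estimate("weighted_median", beta, se, pval_norm(beta, se), J,
                  extra = list(n_boot = n_boot, seed = seed))
}

# Profile log-likelihood of the joint-normal errors-in-variables model:
# beta_exp_j ~ N(gamma_j, se_exp^2), beta_out_j ~ N(beta * gamma_j,
# se_out^2).  For fixed beta the optimal gamma_j is closed-form and the
# profile reduces to a weighted quadratic in the residual beta_out - beta
# * beta_exp.
profile_loglik <- function(beta, pairs) {
  v <- pairs$se_out^2 + beta^2 * pairs$se_exp^2
  -0.5 * sum((pairs$beta_out - beta * pairs$beta_exp)^2 / v)
}

#' Maximum-likelihood estimator
#'
#' Maximizes the joint-normal likelihood of the exposure and outcome
#' effects over the causal effect and the J true SNP-exposure effects,
#' allowing for uncertainty in both associations.  The true effects are
#' profiled out in closed form, leaving a one-dimensional optimization;
#' the SE comes from the observed information (numeric second derivative
#' of the profile log-likelihood).
#'
#' @param pairs `harmonized_pairs` data.frame with at least 2 SNPs.
#' @return an `mr_estimate`.
#' @export
max_likelihood <- function(pairs) {
  check_pairs(pairs, 2, "max_likelihood")
  start <- ivw(pairs, mode = "fixed")$beta
  half <- 1
  for (attempt in seq_len(40)) {
    lo <- start - half
    hi <- start + half
    opt <- stats::optimize(profile_loglik, c(lo, hi), pairs = pairs,
                           maximum = TRUE, tol = 1e-10)
    margin <- 1e-6 * half
    if (opt$maximum > lo + margin && opt$maximum < hi - margin) {
      beta <- opt$maximum
      h <- 1e-5 * (1 + abs(beta))
      d2 <- (profile_loglik(beta + h, pairs) - 2 * profile_loglik(beta, pairs) +
               profile_loglik(beta - h, pairs)) / h^2
      if (!is.finite(d2) || d2 >= 0) {
        stop_mrkit("profile likelihood is not locally concave at the optimum",
                   "mrkit_convergence_error")
      }
      se <- 1 / sqrt(-d2)
      return(new_mr_estimate("mle", beta, se, pval_norm(beta, se), nrow(pairs),
                             extra = list(loglik = opt$objective)))
    }
    half <- half * 2
  }
  stop_mrkit(sprintf("profile-likelihood optimization did not converge; last bracket [%g, %g]",
                     lo, hi),
             "mrkit_convergence_error")
}

huber_psi <- function(t, c = 1.345) pmin(pmax(t, -c), c)

# E[psi(Z) * Z] for Z ~ N(0,1): 1 for the identity score, 2*Phi(c) - 1
# for the Huber score with tuning constant c.
psi_z_moment <- function(loss, c = 1.345) {
  if (loss == "l2") 1 else 2 * stats::pnorm(c) - 1
}

raps_t <- function(beta, tau2, pairs) {
  v <- pairs$se_out^2 + beta^2 * pairs$se_exp^2 + tau2
  list(t = (pairs$beta_out - beta * pairs$beta_exp) / sqrt(v), v = v)
}

# Profile-score component for beta: sum over SNPs of psi(t_j) * d_j with
# d_j = -dt_j/dbeta.  With the identity score and tau2 = 0 this is
# exactly the derivative of the joint-normal profile log-likelihood.
raps_score <- function(beta, tau2, pairs, psi) {
  tt <- raps_t(beta, tau2, pairs)
  d <- pairs$beta_exp / sqrt(tt$v) + tt$t * beta * pairs$se_exp^2 / tt$v
  sum(psi(tt$t) * d)
}

# Overdispersion moment: sum psi(t_j) t_j - J * E[psi(Z) Z] = 0.
raps_tau2_moment <- function(tau2, beta, pairs, psi, delta) {
  tt <- raps_t(beta, tau2, pairs)
  sum(psi(tt$t) * tt$t) - nrow(pairs) * delta
}

expand_uniroot <- function(f, center, ..., tol = 1e-12) {
  half <- 1
  for (attempt in seq_len(60)) {
    lo <- center - half
    hi <- center + half
    flo <- f(lo, ...)
    fhi <- f(hi, ...)
    if (is.finite(flo) && is.finite(fhi) && sign(flo) != sign(fhi)) {
      return(stats::uniroot(f, c(lo, hi), ..., tol = tol)$root)
    }
    half <- half * 2
  }
  stop_mrkit(sprintf("no root found in bracket [%g, %g]", lo, hi),
             "mrkit_convergence_error")
}

#' Robust adjusted profile score (MR-RAPS) estimator
#'
#' Solves the adjusted profile-score estimating equation in the causal
#' effect, standardizing each residual by its full first-order variance
#' `se_out^2 + beta^2 se_exp^2 + tau2` so that weak instruments are
#' handled correctly.  With `overdispersion = TRUE` (default) a
#' systematic-pleiotropy variance `tau2` is estimated jointly from the
#' second-moment equation of the standardized residuals.  The default
#' Huber score (tuning constant 1.345) bounds the influence of outlying
#' instruments; the `"l2"` score with overdispersion off reproduces the
#' profile-likelihood estimate.  SE by the M-estimation sandwich formula.
#'
#' @param pairs `harmonized_pairs` data.frame with at least 3 SNPs.
#' @param loss `"huber"` (default) or `"l2"`.
#' @param overdispersion estimate the pleiotropy variance `tau2`
#'   (default `TRUE`).
#' @return an `mr_estimate`; `extra` carries `tau2` and the loss.
#' @export
mr_raps <- function(pairs, loss = c("huber", "l2"), overdispersion = TRUE) {
  loss <- match.arg(loss)
  check_pairs(pairs, 3, "mr_raps")
  psi <- if (loss == "huber") huber_psi else identity
  delta <- psi_z_moment(loss)

  beta <- ivw(pairs, mode = "fixed")$beta
  tau2 <- 0
  for (iter in seq_len(200)) {
    beta_new <- expand_uniroot(raps_score, beta, tau2 = tau2, pairs = pairs,
                               psi = psi)
    tau2_new <- tau2
    if (overdispersion) {
      m0 <- raps_tau2_moment(0, beta_new, pairs, psi, delta)
      if (m0 <= 0) {
        # residuals already under-dispersed: no extra variance needed
        tau2_new <- 0
      } else {
        upper <- stats::median(pairs$se_out^2)
        while (raps_tau2_moment(upper, beta_new, pairs, psi, delta) > 0 &&
               upper < 1e8) {
          upper <- upper * 4
        }
        tau2_new <- stats::uniroot(raps_tau2_moment, c(0, upper),
                                   beta = beta_new, pairs = pairs, psi = psi,
                                   delta = delta, tol = 1e-12)$root
      }
    }
    done <- abs(beta_new - beta) < 1e-10 * (1 + abs(beta_new)) &&
      abs(tau2_new - tau2) < 1e-10 * (1 + tau2_new)
    beta <- beta_new
    tau2 <- tau2_new
    if (done) break
  }

  tt <- raps_t(beta, tau2, pairs)
  d <- pairs$beta_exp / sqrt(tt$v) + tt$t * beta * pairs$se_exp^2 / tt$v
  B <- sum((psi(tt$t) * d)^2)
  h <- 1e-6 * (1 + abs(beta))
  A <- (raps_score(beta + h, tau2, pairs, psi) -
          raps_score(beta - h, tau2, pairs, psi)) / (2 * h)
  se <- sqrt(B) / abs(A)
  new_mr_estimate("raps", beta, se, pval_norm(beta, se), nrow(pairs),
                  extra = list(tau2 = tau2, loss = loss,
                               overdispersion = overdispersion))
}

#' Refresh the odds-ratio presentation of an estimate
#'
#' Recomputes the 95% CI as `beta +/- 1.96 se` and fills the exponentiated
#' odds-ratio fields.  Stored values are never rounded; rounding belongs
#' to presentation only.
#'
#' @param est an `mr_estimate`.
#' @return the estimate with `ci_low`, `ci_high`, `or`, `or_low`,
#'   `or_high` refilled.
#' @export
to_odds_ratio <- function(est) {
  stopifnot(inherits(est, "mr_estimate"), est$se > 0)
  est$ci_low <- est$beta - stats::qnorm(0.975) * est$se
  est$ci_high <- est$beta + stats::qnorm(0.975) * est$se
  est$or <- exp(est$beta)
  est$or_low <- exp(est$ci_low)
  est$or_high <- exp(est$ci_high)
  est
}

#' Tidy table of MR estimates
#'
#' @param estimates list of `mr_estimate` objects.
#' @return data.frame with columns `method`, `nsnp`, `b`, `se`, `ci_low`,
#'   `ci_high`, `pval`, `or`, `or_lci95`, `or_uci95`.
#' @export
mr_estimates_table <- function(estimates) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(method = e$method, nsnp = e$n_snps, b = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               or = e$or, or_lci95 = e$or_low, or_uci95 = e$or_high,
               stringsAsFactors = FALSE)
  }))
}
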