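# Heterogeneity, pleiotropy, outlier and influence diagnostics.

#' Cochran's Q heterogeneity test
#'
#' On the IVW basis, `Q = sum(w_j (ratio_j - beta_IVW)^2)` over the
#' per-SNP Wald ratios with first-order inverse-variance weights,
#' referred to chi-square with `J - 1` df.  On the Egger basis, Rucker's
#' Q': the weighted residual sum of squares about the oriented MR-Egger
#' fit, with `J - 2` df.
#'
#' @param pairs `harmonized_pairs` data.frame.
#' @param basis `"ivw"` (default) or `"egger"`.
#' @return list of class `heterogeneity_result`: `basis`, `Q`, `df`,
#'   `pval`.
#' @export
cochran_q <- function(pairs, basis = c("ivw", "egger")) {
  basis <- match.arg(basis)
  if (basis == "ivw") {
    check_pairs(pairs, 2, "cochran_q (ivw basis)")
    w <- ivw_weights(pairs)
    ratio <- pairs$beta_out / pairs$beta_exp
    b <- sum(w * ratio) / sum(w)
    Q <- sum(w * (ratio - b)^2)
    df <- nrow(pairs) - 1L
  } else {
    check_pairs(pairs, 3, "cochran_q (egger basis)")
    flip <- pairs$beta_exp < 0
    x <- abs(pairs$beta_exp)
    y <- ifelse(flip, -pairs$beta_out, pairs$beta_out)
    w <- 1 / pairs$se_out^2
    fit <- wls_floored(cbind(1, x), y, w, df = nrow(pairs) - 2)
    Q <- fit$rss
    df <- nrow(pairs) - 2L
  }
  structure(list(basis = basis, Q = Q, df = df,
                 pval = stats::pchisq(Q, df, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q (%s basis): Q = %.3f, df = %d, p = %.3g\n",
              x$basis, x$Q, x$df, x$pval))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept row of the MR-Egger regression: a nonzero intercept
#' indicates a systematic direct (pleiotropic) effect shared by the
#' instruments.  P-value from t with `J - 2` df; `pleiotropy` flags
#' `p < 0.05`.
#'
#' @param pairs `harmonized_pairs` data.frame with at least 3 SNPs.
#' @return list: `intercept`, `se`, `pval`, `pleiotropy`.
#' @export
egger_intercept_test <- function(pairs) {
  fit <- mr_egger(pairs)
  list(intercept = fit$extra$intercept,
       se = fit$extra$intercept_se,
       pval = fit$extra$intercept_pval,
       pleiotropy = fit$extra$intercept_pval < 0.05)
}

# Weighted through-origin slope (the PRESSO working model).
presso_slope <- function(x, y, w) sum(w * x * y) / sum(w * x^2)

#' MR-PRESSO global, outlier and distortion tests
#'
#' Simulation-based pleiotropy residual sum of squares test.  The global
#' statistic is the weighted RSS of each SNP about the leave-one-out IVW
#' prediction; its null distribution comes from `n_sim` parametric
#' simulations of the exposure and outcome effects under the
#' no-pleiotropy model.  When the global test is significant, each SNP's
#' observed squared residual is compared with its own simulated
#' distribution for the outlier test (Bonferroni-corrected across the J
#' SNPs; the per-SNP p-values are reported either way).  When outliers
#' are found,
#' the IVW estimate is recomputed without them and a distortion test
#' compares the raw-vs-corrected shift against shifts from removing
#' random subsets of the same size.  Empirical p-values use the
#' `(1 + exceedances) / (1 + n_sim)` rule so they are never zero.
#'
#' @param pairs `harmonized_pairs` data.frame with at least 4 SNPs.
#' @param n_sim simulation draws (at least 500; default 1,000).
#' @param significance outlier significance level after Bonferroni
#'   correction (default 0.05).
#' @param seed integer seed; all randomness derives from it.
#' @return list of class `presso_result`: `global_rss_obs`, `global_p`,
#'   `n_sim`, `outlier_table` (per-SNP raw and Bonferroni p),
#'   `outlier_snps`, `distortion_p`, `estimate_raw`,
#'   `estimate_outlier_corrected`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, significance = 0.05, seed) {
  check_pairs(pairs, 4, "mr_presso")
  if (n_sim < 500) {
    stop_mrkit("n_sim must be at least 500", "mrkit_config_error")
  }
  if (missing(seed)) {
    stop_mrkit("mr_presso requires an explicit seed", "mrkit_config_error")
  }
  J <- nrow(pairs)
  x <- pairs$beta_exp; y <- pairs$beta_out
  sx <- pairs$se_exp; sy <- pairs$se_out
  w <- 1 / sy^2

  loo_slope <- function(xv, yv) {
    sxy <- sum(w * xv * yv); sxx <- sum(w * xv^2)
    (sxy - w * xv * yv) / (sxx - w * xv^2)
  }
  b_loo <- loo_slope(x, y)
  resid_obs <- w * (y - b_loo * x)^2
  rss_obs <- sum(resid_obs)

  sims <- with_seed(derive_seed(seed, 1), {
    X <- matrix(stats::rnorm(n_sim * J, rep(x, each = n_sim),
                             rep(sx, each = n_sim)), n_sim, J)
    Y <- matrix(stats::rnorm(n_sim * J, rep(b_loo * x, each = n_sim),
                             rep(sy, each = n_sim)), n_sim, J)
    XY <- sweep(X * Y, 2, w, "*")
    XX <- sweep(X * X, 2, w, "*")
    sxy <- rowSums(XY); sxx <- rowSums(XX)
    B <- (sxy - XY) / (sxx - XX)      # n_sim x J leave-one-out slopes
    R <- sweep((Y - B * X)^2, 2, w, "*")
    list(rss = rowSums(R), resid = R)
  })

  global_p <- (1 + sum(sims$rss >= rss_obs)) / (1 + n_sim)
  p_raw <- (1 + colSums(sweep(sims$resid, 2, resid_obs, ">="))) / (1 + n_sim)
  p_bonf <- pmin(1, p_raw * J)
  # per the two-stage design, per-SNP outlier calls are only made when the
  # global test detects pleiotropy; the per-SNP p-values stay reported
  outlier_table <- data.frame(SNP = pairs$SNP, p_raw = p_raw,
                              p_bonferroni = p_bonf,
                              outlier = global_p < significance &
                                p_bonf < significance,
                              stringsAsFactors = FALSE)
  outlier_snps <- outlier_table$SNP[outlier_table$outlier]

  estimate_raw <- ivw(pairs)
  estimate_corrected <- NULL
  distortion_p <- NA_real_
  n_out <- length(outlier_snps)
  if (n_out > 0 && J - n_out >= 2) {
    keep <- !(pairs$SNP %in% outlier_snps)
    estimate_corrected <- ivw(pairs[keep, , drop = FALSE])
    d_obs <- estimate_raw$beta - estimate_corrected$beta
    # the IVW point estimate equals the weighted through-origin slope, so
    # subset estimates reduce to running-sum updates
    wxy <- w * x * y; wxx <- w * x^2
    txy <- sum(wxy); txx <- sum(wxx)
    d_sim <- with_seed(derive_seed(seed, 2), {
      vapply(seq_len(n_sim), function(i) {
        drop_idx <- sample.int(J, n_out)
        estimate_raw$beta -
          (txy - sum(wxy[drop_idx])) / (txx - sum(wxx[drop_idx]))
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (1 + n_sim)
  }

  structure(list(global_rss_obs = rss_obs, global_p = global_p,
                 n_sim = n_sim, outlier_table = outlier_table,
                 outlier_snps = outlier_snps, distortion_p = distortion_p,
                 estimate_raw = estimate_raw,
                 estimate_outlier_corrected = estimate_corrected,
                 seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.3f, p = %.4g (%d sims)\n",
              x$global_rss_obs, x$global_p, x$n_sim))
  if (length(x$outlier_snps) > 0) {
    cat("Outliers:", paste(x$outlier_snps, collapse = ", "),
        sprintf("; distortion p = %.3g\n", x$distortion_p))
  } else {
    cat("No outliers detected\n")
  }
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW causal effect J times, each time omitting one
#' SNP, to reveal instruments that single-handedly drive the result.
#' Each entry equals an independent [ivw()] call on the corresponding
#' subset.
#'
#' @param pairs `harmonized_pairs` data.frame with at least 3 SNPs.
#' @param method currently only `"ivw"`.
#' @param mode IVW mode passed through (default `"mre"`).
#' @return data.frame of class `loo_series` with one row per omitted SNP:
#'   `SNP`, `beta`, `se`, `pval`.
#' @export
leave_one_out <- function(pairs, method = c("ivw"), mode = "mre") {
  match.arg(method)
  check_pairs(pairs, 3, "leave_one_out")
  rows <- lapply(seq_len(nrow(pairs)), function(j) {
    est <- ivw(pairs[-j, , drop = FALSE], mode = mode)
    data.frame(SNP = pairs$SNP[j], beta = est$beta, se = est$se,
               pval = est$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("loo_series", "data.frame")
  out
}
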