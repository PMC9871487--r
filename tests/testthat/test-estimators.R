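test_that("Wald ratio: point estimate, SE options, degenerate instrument", {
  pair <- pairs_from(beta_exp = 0.1, beta_out = 0.2, se_exp = 0.02,
                     se_out = 0.05)
  est <- wald_ratio(pair)
  expect_equal(est$beta, 2.0)
  expect_equal(est$se, 0.5)
  expect_equal(est$n_snps, 1L)

  null <- wald_ratio(pairs_from(beta_exp = 0.1, beta_out = 0, se_out = 0.05))
  expect_equal(null$beta, 0)
  expect_equal(null$or, 1)

  # second-order SE against the delta-method formula
  est2 <- wald_ratio(pair, se_method = "second")
  expect_equal(est2$se,
               sqrt(0.05^2 / 0.1^2 + 0.2^2 * 0.02^2 / 0.1^4),
               tolerance = 1e-12)

  expect_error(wald_ratio(pairs_from(beta_exp = 0, beta_out = 0.1)),
               class = "mrkit_degenerate_instrument")
})

test_that("IVW: delegation, equal-weight average, WLS oracle agreement", {
  # one SNP routes through the Wald ratio
  one <- pairs_from(beta_exp = 0.1, beta_out = 0.2, se_out = 0.05)
  expect_equal(ivw(one)$beta, wald_ratio(one)$beta)
  expect_equal(ivw(one)$se, wald_ratio(one)$se)
  expect_equal(ivw(one)$method, "wald_ratio")

  # ratios 1 and 3 with equal ratio SE 1: mean 2, fixed se 1/sqrt(2)
  two <- pairs_from(beta_exp = c(1, 1), beta_out = c(1, 3), se_out = 1)
  est <- ivw(two, mode = "fixed")
  expect_equal(est$beta, 2)
  expect_equal(est$se, 1 / sqrt(2))

  # random instances against the lm-based WLS-through-origin oracle
  for (seed in c(2, 5, 9)) {
    pairs <- make_pairs(J = 50, seed = seed, beta = 0.15)
    oracle <- wls_oracle(pairs, intercept = FALSE)
    est <- ivw(pairs)
    expect_equal(est$beta, unname(oracle$coef), tolerance = 1e-10)
    expect_equal(est$se, unname(oracle$se), tolerance = 1e-10)
  }

  err <- tryCatch(ivw(pairs_from(beta_exp = c(0, 1), beta_out = c(1, 1))),
                  mrkit_degenerate_instrument = function(e) e)
  expect_s3_class(err, "mrkit_degenerate_instrument")
  expect_match(conditionMessage(err), "rs001")
})

test_that("MR-Egger: exact interpolation, oracle agreement, collinearity", {
  # exact linear data is interpolated exactly
  exact <- pairs_from(beta_exp = c(1, 2, 3),
                      beta_out = 0.5 + 1.5 * c(1, 2, 3), se_out = 0.1)
  fit <- mr_egger(exact)
  expect_equal(fit$beta, 1.5, tolerance = 1e-10)
  expect_equal(fit$extra$intercept, 0.5, tolerance = 1e-10)

  for (seed in c(3, 6, 8)) {
    pairs <- make_pairs(J = 50, seed = seed, beta = 0.1,
                        alpha = rnorm(50, 0.01, 0.01))
    oracle <- wls_oracle(pairs, intercept = TRUE)
    fit <- mr_egger(pairs)
    expect_equal(fit$beta, unname(oracle$coef[2]), tolerance = 1e-10)
    expect_equal(fit$se, unname(oracle$se[2]), tolerance = 1e-10)
    expect_equal(fit$extra$intercept, unname(oracle$coef[1]), tolerance = 1e-10)
    expect_equal(fit$extra$intercept_se, unname(oracle$se[1]), tolerance = 1e-10)
  }

  expect_error(mr_egger(pairs_from(beta_exp = c(1, 1, 1),
                                   beta_out = c(1, 2, 3))),
               class = "mrkit_collinear_design")
  expect_error(mr_egger(pairs_from(beta_exp = c(1, 2), beta_out = c(1, 2))),
               class = "mrkit_insufficient_instruments")
})

test_that("weighted median: interpolation oracle and seeded determinism", {
  # symmetric case
  sym <- pairs_from(beta_exp = c(1, 1, 1), beta_out = c(1, 2, 3), se_out = 1)
  expect_equal(weighted_median(sym, n_boot = 100, seed = 1)$beta, 2)

  # hand-executed cumulative-midpoint interpolation: weights (.5,.3,.2)
  # over ratios (1,2,3) -> midpoints (.25,.65,.9) -> 1.625 at s = 0.5
  w <- c(0.5, 0.3, 0.2)
  se_out <- 1 / sqrt(w)           # beta_exp = 1 so weights are 1/se_out^2
  wm <- pairs_from(beta_exp = c(1, 1, 1), beta_out = c(1, 2, 3),
                   se_out = se_out)
  expect_equal(weighted_median(wm, n_boot = 100, seed = 1)$beta, 1.625)

  # same seed, bit-identical; explicit seed is mandatory
  pairs <- make_pairs(J = 12, seed = 4)
  a <- weighted_median(pairs, n_boot = 200, seed = 77)
  b <- weighted_median(pairs, n_boot = 200, seed = 77)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  expect_error(weighted_median(pairs, n_boot = 200),
               class = "mrkit_config_error")
  expect_error(weighted_median(pairs, n_boot = 50, seed = 1),
               class = "mrkit_config_error")
})

test_that("MLE: IVW limit, grid-search oracle, constructed-instance recovery", {
  # se_exp -> 0 collapses the profile likelihood onto fixed-effect IVW
  pairs <- make_pairs(J = 20, seed = 10)
  pairs$se_exp <- 1e-8
  expect_equal(max_likelihood(pairs)$beta, ivw(pairs, mode = "fixed")$beta,
               tolerance = 1e-4)

  # brute-force grid over beta in [-2, 2], step 1e-4
  pairs <- make_pairs(J = 20, seed = 21, beta = 0.3, se_exp = 0.01,
                      se_out = 0.01)
  grid <- seq(-2, 2, by = 1e-4)
  ll <- vapply(grid, function(b) {
    v <- pairs$se_out^2 + b^2 * pairs$se_exp^2
    -0.5 * sum((pairs$beta_out - b * pairs$beta_exp)^2 / v)
  }, numeric(1))
  expect_lt(abs(max_likelihood(pairs)$beta - grid[which.max(ll)]), 1e-4)

  # two exactly-consistent instruments recover the causal effect
  tiny <- pairs_from(beta_exp = c(0.05, 0.08),
                     beta_out = 0.4 * c(0.05, 0.08) + c(1e-5, -1e-5),
                     se_exp = 0.001, se_out = 0.001)
  expect_equal(max_likelihood(tiny)$beta, 0.4, tolerance = 1e-3)
})

test_that("MR-RAPS: MLE equivalence, outlier robustness, clean recovery", {
  pairs <- make_pairs(J = 20, seed = 31, beta = 0.1)
  expect_equal(mr_raps(pairs, loss = "l2", overdispersion = FALSE)$beta,
               max_likelihood(pairs)$beta, tolerance = 1e-4)

  # a planted outlier pulls the l2 fit more than the Huber fit
  out <- pairs_from(beta_exp = rep(0.05, 10),
                    beta_out = c(0.05 * 10, rep(0.05 * 2, 9)),
                    se_exp = 0.002, se_out = 0.002)
  huber <- mr_raps(out, loss = "huber")$beta
  l2 <- mr_raps(out, loss = "l2")$beta
  expect_lt(abs(huber - 2), abs(l2 - 2))

  clean <- make_pairs(J = 50, seed = 12, beta = 0.1)
  est <- mr_raps(clean)
  expect_lt(abs(est$beta - 0.1), 3 * est$se)
})

test_that("odds-ratio transform and presentation round trip", {
  z <- qnorm(0.975)
  e0 <- to_odds_ratio(ivw(pairs_from(beta_exp = c(1, 1), beta_out = c(0, 0),
                                     se_out = 1)))
  expect_equal(e0$or, 1)
  expect_equal(e0$or_low, exp(-z * e0$se))
  expect_equal(e0$or_high, exp(z * e0$se))

  # published-style OR 1.11 (1.01-1.22) round-trips through the log scale
  beta <- log(1.11)
  se <- (log(1.22) - log(1.01)) / (2 * z)
  est <- structure(
    list(method = "ivw", beta = beta, se = se, ci_low = NA, ci_high = NA,
         pval = 0.03, n_snps = 15L, extra = list()),
    class = "mr_estimate")
  est <- to_odds_ratio(est)
  expect_equal(round(est$or, 2), 1.11)
  expect_equal(round(est$or_low, 2), 1.01)
  expect_equal(round(est$or_high, 2), 1.22)

  est2 <- structure(list(method = "ivw", beta = -0.5, se = 0.1,
                         pval = 0.01, n_snps = 5L, extra = list()),
                    class = "mr_estimate")
  est2 <- to_odds_ratio(est2)
  expect_equal(est2$or, exp(-0.5), tolerance = 1e-12)
  expect_equal(est2$or_low, exp(-0.5 - z * 0.1), tolerance = 1e-12)
  expect_equal(est2$or_high, exp(-0.5 + z * 0.1), tolerance = 1e-12)
})

test_that("sign and scale equivariance hold across estimators", {
  pairs <- make_pairs(J = 15, seed = 8, beta = 0.2)
  neg <- pairs; neg$beta_out <- -neg$beta_out

  expect_equal(ivw(neg)$beta, -ivw(pairs)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(neg)$beta, -mr_egger(pairs)$beta, tolerance = 1e-12)
  expect_equal(max_likelihood(neg)$beta, -max_likelihood(pairs)$beta,
               tolerance = 1e-6)
  expect_equal(mr_raps(neg)$beta, -mr_raps(pairs)$beta, tolerance = 1e-8)
  expect_equal(weighted_median(neg, n_boot = 100, seed = 5)$beta,
               -weighted_median(pairs, n_boot = 100, seed = 5)$beta,
               tolerance = 1e-8)

  # multiplying exposure effects by c divides ratio estimates by c
  sc <- pairs; sc$beta_exp <- 3 * sc$beta_exp; sc$se_exp <- 3 * sc$se_exp
  expect_equal(ivw(sc)$beta, ivw(pairs)$beta / 3, tolerance = 1e-12)
  expect_equal(max_likelihood(sc)$beta, max_likelihood(pairs)$beta / 3,
               tolerance = 1e-5)
  expect_equal(weighted_median(sc, n_boot = 100, seed = 5)$beta,
               weighted_median(pairs, n_boot = 100, seed = 5)$beta / 3,
               tolerance = 1e-8)
})

test_that("estimates serialize to the tidy table layout", {
  pairs <- make_pairs(J = 10, seed = 2)
  tab <- mr_estimates_table(list(ivw(pairs), mr_egger(pairs)))
  expect_equal(names(tab), c("method", "nsnp", "b", "se", "ci_low", "ci_high",
                             "pval", "or", "or_lci95", "or_uci95"))
  expect_equal(tab$method, c("ivw", "egger"))
  expect_equal(tab$or, exp(tab$b))
})
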