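# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

# Minimal harmonized instrument set drawn from the summary-statistics
# model: beta_exp_j ~ N(gamma_j, se_exp^2), beta_out_j ~ N(beta * gamma_j
# + alpha_j, se_out^2).  Bypasses table I/O for speed; the full
# table-based path is exercised via simulate_gwas_pair().
make_pairs <- function(J = 10, seed = 1, beta = 0.1, gamma_sd = 0.05,
                       se_exp = 0.005, se_out = 0.005,
                       alpha = rep(0, J), n_exp = 1e5, n_out = 1e5) {
  withr::with_seed(seed, {
    # exposure-increasing allele convention, as in simulate_gwas_pair()
    gamma <- abs(rnorm(J, 0, gamma_sd))
    data.frame(
      SNP = sprintf("rs%03d", seq_len(J)),
      beta_exp = rnorm(J, gamma, se_exp),
      se_exp = rep(se_exp, length.out = J),
      beta_out = rnorm(J, beta * gamma + alpha, se_out),
      se_out = rep(se_out, length.out = J),
      eaf_exp = NA_real_, eaf_out = NA_real_,
      n_exp = n_exp, n_out = n_out,
      stringsAsFactors = FALSE
    )
  })
}

# Hand-built harmonized pairs from explicit vectors.
pairs_from <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.05,
                       n_exp = 1e5, n_out = 1e5) {
  J <- length(beta_exp)
  data.frame(
    SNP = sprintf("rs%03d", seq_len(J)),
    beta_exp = beta_exp, se_exp = rep(se_exp, length.out = J),
    beta_out = beta_out, se_out = rep(se_out, length.out = J),
    eaf_exp = NA_real_, eaf_out = NA_real_,
    n_exp = n_exp, n_out = n_out,
    stringsAsFactors = FALSE
  )
}

# A small well-formed summary-statistics table.
make_sumstats <- function(snp = c("rs1", "rs2", "rs3"),
                          chr = "1", pos = c(1000L, 2000L, 3000L),
                          ea = c("A", "C", "G"), oa = c("G", "T", "A"),
                          eaf = c(0.2, 0.3, 0.4),
                          beta = c(0.10, -0.05, 0.02),
                          se = c(0.01, 0.02, 0.01),
                          n = 10000L) {
  p <- 2 * pnorm(-abs(beta / se))
  data.frame(SNP = snp, CHR = chr, POS = pos, EA = ea, OA = oa, EAF = eaf,
             BETA = beta, SE = se, P = p, N = n, stringsAsFactors = FALSE)
}

# Independent weighted-least-squares oracle via stats::lm, with the
# residual variance factor floored at 1 as fixed/multiplicative
# random-effects meta-analysis does.
wls_oracle <- function(pairs, intercept = FALSE) {
  w <- 1 / pairs$se_out^2
  if (intercept) {
    flip <- pairs$beta_exp < 0
    x <- abs(pairs$beta_exp)
    y <- ifelse(flip, -pairs$beta_out, pairs$beta_out)
    fit <- lm(y ~ x, weights = w)
  } else {
    x <- pairs$beta_exp
    y <- pairs$beta_out
    fit <- lm(y ~ x + 0, weights = w)
  }
  sm <- summary(fit)
  coefs <- sm$coefficients
  # lm scales coefficient SEs by the residual sigma; floor it at 1
  list(coef = coefs[, 1],
       se = coefs[, 2] / sm$sigma * max(sm$sigma, 1),
       sigma = sm$sigma)
}

# Harmonized pairs straight from a simulated table pair (generated with
# swap_fraction = 0 and no palindromes, so the tables are already aligned).
pairs_from_sim <- function(sim) {
  data.frame(SNP = sim$exposure$SNP,
             beta_exp = sim$exposure$BETA, se_exp = sim$exposure$SE,
             beta_out = sim$outcome$BETA, se_out = sim$outcome$SE,
             eaf_exp = sim$exposure$EAF, eaf_out = sim$outcome$EAF,
             n_exp = sim$exposure$N, n_out = sim$outcome$N,
             stringsAsFactors = FALSE)
}
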