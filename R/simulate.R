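# Synthetic GWAS summary-statistics generator.
#
# Emulates the statistical structure a two-sample MR analysis assumes:
# per-SNP effects observed with sampling noise scaled by allele frequency
# and sample size, a causal effect linking exposure to outcome, optional
# horizontal pleiotropy (balanced or directional), null SNPs and LD
# blocks.  Every draw derives from one master seed via per-component
# sub-streams, so enlarging the panel never reshuffles earlier draws.

normalize_ld_blocks <- function(ld_blocks) {
  if (is.null(ld_blocks) || length(ld_blocks) == 0) {
    return(data.frame(size = integer(0), r2 = numeric(0)))
  }
  out <- do.call(rbind, lapply(ld_blocks, function(b) {
    b <- as.list(b)
    data.frame(size = as.integer(b$size), r2 = as.numeric(b$r2))
  }))
  if (any(out$size < 1)) {
    stop_mrkit("LD block sizes must be positive", "mrkit_config_error")
  }
  if (any(out$r2 < 0 | out$r2 > 1)) {
    stop_mrkit("LD block r-squared must lie in [0, 1]", "mrkit_config_error")
  }
  out
}

#' Configuration for a synthetic exposure/outcome GWAS pair
#'
#' The generative model, per causal SNP j with minor-allele frequency
#' `f_j ~ U(maf_range)`:
#' * true SNP-exposure effect `gamma_j = |N(0, gamma_sd^2)|` — the
#'   magnitude of a centred normal draw, reported on the
#'   exposure-increasing allele as instrument tables conventionally are
#'   (directional pleiotropy is only meaningful relative to a fixed
#'   allele orientation);
#' * direct (pleiotropic) outcome effect `alpha_j`, zero under mode
#'   `"none"`, `N(pleio_mean, pleio_sd^2)` otherwise (`pleio_mean` forced
#'   to 0 under `"balanced"`), applied to a fraction `pleio_frac` of the
#'   causal SNPs;
#' * sampling SEs `se = 1 / sqrt(2 n f (1 - f))` (standardized-trait
#'   scale);
#' * observed effects `beta_exp ~ N(gamma_j, se_exp^2)` and
#'   `beta_out ~ N(true_beta * gamma_j + alpha_j, se_out^2)`.
#'
#' Null SNPs have `gamma_j = alpha_j = 0` in both traits.  By default
#' `alpha_j` is drawn independently of `gamma_j`, so the InSIDE
#' assumption holds by construction; `pleio_gamma_cor` introduces a
#' correlation to demonstrate MR-Egger failure modes.
#'
#' @param n_causal number of causal (instrument-candidate) SNPs.
#' @param n_null number of SNPs with no effect on either trait.
#' @param true_beta causal effect of exposure on outcome (log-odds scale).
#' @param gamma_sd SD of the true SNP-exposure effects.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleio_mean,pleio_sd mean and SD of the direct effects.
#' @param pleio_frac fraction of causal SNPs receiving a direct effect.
#' @param pleio_gamma_cor correlation between `alpha_j` and `gamma_j`
#'   (0 keeps InSIDE intact).
#' @param n_exp,n_out exposure and outcome GWAS sample sizes.
#' @param maf_range minor-allele-frequency interval within (0, 0.5].
#' @param ld_blocks list of LD blocks, each `list(size =, r2 =)`; SNPs are
#'   assigned to blocks in table order, remaining SNPs are independent.
#' @param palindromic_fraction fraction of SNPs given A/T or C/G alleles
#'   (for harmonization tests).
#' @param swap_fraction fraction of outcome records reported on the
#'   opposite allele ordering (beta negated, EAF flipped), exercising
#'   harmonization.
#' @param seed master integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_causal = 50, n_null = 0, true_beta = 0.1,
                       gamma_sd = 0.05,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleio_mean = 0, pleio_sd = 0, pleio_frac = 1,
                       pleio_gamma_cor = 0,
                       n_exp = 1e5, n_out = 1e5,
                       maf_range = c(0.05, 0.5),
                       ld_blocks = NULL,
                       palindromic_fraction = 0,
                       swap_fraction = 0.3,
                       seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (n_causal < 1) stop_mrkit("n_causal must be positive", "mrkit_config_error")
  if (n_null < 0) stop_mrkit("n_null must be non-negative", "mrkit_config_error")
  if (gamma_sd < 0 || pleio_sd < 0) {
    stop_mrkit("SDs must be non-negative", "mrkit_config_error")
  }
  if (pleiotropy_mode == "balanced" && pleio_mean != 0) {
    stop_mrkit("balanced pleiotropy requires pleio_mean = 0", "mrkit_config_error")
  }
  if (pleiotropy_mode == "none") {
    pleio_mean <- 0; pleio_sd <- 0; pleio_frac <- 0
  }
  if (pleio_frac < 0 || pleio_frac > 1) {
    stop_mrkit("pleio_frac must lie in [0, 1]", "mrkit_config_error")
  }
  if (abs(pleio_gamma_cor) > 1) {
    stop_mrkit("pleio_gamma_cor must lie in [-1, 1]", "mrkit_config_error")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop_mrkit("maf_range must be an interval within (0, 0.5]", "mrkit_config_error")
  }
  if (n_exp <= 3 || n_out <= 3) {
    stop_mrkit("sample sizes must exceed 3", "mrkit_config_error")
  }
  if (palindromic_fraction < 0 || palindromic_fraction > 1 ||
      swap_fraction < 0 || swap_fraction > 1) {
    stop_mrkit("fractions must lie in [0, 1]", "mrkit_config_error")
  }
  blocks <- normalize_ld_blocks(ld_blocks)
  if (sum(blocks$size) > n_causal + n_null) {
    stop_mrkit("LD block sizes exceed the SNP count", "mrkit_config_error")
  }
  structure(list(
    n_causal = as.integer(n_causal), n_null = as.integer(n_null),
    true_beta = true_beta, gamma_sd = gamma_sd,
    pleiotropy_mode = pleiotropy_mode, pleio_mean = pleio_mean,
    pleio_sd = pleio_sd, pleio_frac = pleio_frac,
    pleio_gamma_cor = pleio_gamma_cor,
    n_exp = n_exp, n_out = n_out, maf_range = maf_range,
    ld_blocks = blocks,
    palindromic_fraction = palindromic_fraction,
    swap_fraction = swap_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                               ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)

# Chromosome/position layout: each LD block (and each independent SNP)
# gets its own 30 Mb locus so distinct blocks always exceed the default
# 10 Mb clumping window; SNPs within a block sit 1 kb apart.
assign_positions <- function(n_snps, blocks) {
  block_id <- integer(n_snps)
  offset <- 0L
  b <- 0L
  if (nrow(blocks) > 0) {
    for (i in seq_len(nrow(blocks))) {
      b <- b + 1L
      block_id[offset + seq_len(blocks$size[i])] <- b
      offset <- offset + blocks$size[i]
    }
  }
  for (j in seq_len(n_snps - offset)) {
    b <- b + 1L
    block_id[offset + j] <- b
  }
  within <- stats::ave(seq_len(n_snps), block_id, FUN = seq_along)
  chrom <- as.character(((block_id - 1L) %% 22L) + 1L)
  pos <- 1e6 + ((block_id - 1L) %/% 22L) * 3e7 + (within - 1L) * 1000
  list(chrom = chrom, pos = pos, block_id = block_id)
}

#' Simulate an exposure/outcome GWAS summary-statistics pair
#'
#' Draws a full pair of summary-statistics tables plus a truth record
#' under the generative model of [sim_config()].  Deterministic given the
#' config: the same config reproduces the tables bit-for-bit, and each
#' model component (MAF, effects, noise, alleles) draws from its own
#' seed sub-stream.
#'
#' @param config a `sim_config`.
#' @return list with `exposure` and `outcome` (canonical
#'   summary-statistics data.frames), `truth` (per-SNP `SNP`, `gamma`,
#'   `alpha`, `maf`, `causal`, plus the causal effect as attribute
#'   `"true_beta"`) and `config`.
#' @export
simulate_gwas_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_causal + config$n_null
  causal <- c(rep(TRUE, config$n_causal), rep(FALSE, config$n_null))
  snp <- sprintf("rs%06d", seq_len(n))
  layout <- assign_positions(n, config$ld_blocks)

  f <- with_seed(derive_seed(config$seed, 1),
                 stats::runif(n, config$maf_range[1], config$maf_range[2]))
  # effect alleles are reported as the exposure-increasing allele (the
  # usual convention for instrument tables), so the true SNP-exposure
  # effect is the magnitude of a N(0, gamma_sd^2) draw
  gamma <- numeric(n)
  gamma[causal] <- abs(with_seed(derive_seed(config$seed, 2),
                                 stats::rnorm(config$n_causal, 0,
                                              config$gamma_sd)))
  alpha <- numeric(n)
  if (config$pleiotropy_mode != "none" && config$pleio_frac > 0) {
    u <- with_seed(derive_seed(config$seed, 3), stats::runif(config$n_causal))
    z <- with_seed(derive_seed(config$seed, 8), stats::rnorm(config$n_causal))
    has_pleio <- u < config$pleio_frac
    rho <- config$pleio_gamma_cor
    a <- config$pleio_mean +
      rho * (config$pleio_sd / max(config$gamma_sd, 1e-12)) * gamma[causal] +
      sqrt(1 - rho^2) * config$pleio_sd * z
    alpha[causal] <- ifelse(has_pleio, a, 0)
  }

  se_exp <- 1 / sqrt(2 * config$n_exp * f * (1 - f))
  se_out <- 1 / sqrt(2 * config$n_out * f * (1 - f))
  beta_exp <- gamma + se_exp *
    with_seed(derive_seed(config$seed, 4), stats::rnorm(n))
  beta_out <- config$true_beta * gamma + alpha + se_out *
    with_seed(derive_seed(config$seed, 5), stats::rnorm(n))

  alleles <- with_seed(derive_seed(config$seed, 6), {
    pal <- stats::runif(n) < config$palindromic_fraction
    pick <- function(pairs, k) pairs[sample.int(nrow(pairs), k, replace = TRUE), , drop = FALSE]
    ea <- character(n); oa <- character(n)
    if (any(pal)) {
      pp <- pick(PALINDROMIC_PAIRS, sum(pal))
      ea[pal] <- pp[, 1]; oa[pal] <- pp[, 2]
    }
    np <- pick(NONPALINDROMIC_PAIRS, sum(!pal))
    ea[!pal] <- np[, 1]; oa[!pal] <- np[, 2]
    list(ea = ea, oa = oa)
  })
  swap <- with_seed(derive_seed(config$seed, 7),
                    stats::runif(n) < config$swap_fraction)

  make_table <- function(beta, se, n_samp, flip) {
    data.frame(
      SNP = snp, CHR = layout$chrom, POS = layout$pos,
      EA = ifelse(flip, alleles$oa, alleles$ea),
      OA = ifelse(flip, alleles$ea, alleles$oa),
      EAF = ifelse(flip, 1 - f, f),
      BETA = ifelse(flip, -beta, beta),
      SE = se,
      P = pval_norm(beta, se),
      N = n_samp,
      stringsAsFactors = FALSE
    )
  }
  exposure <- make_table(beta_exp, se_exp, config$n_exp, rep(FALSE, n))
  outcome <- make_table(beta_out, se_out, config$n_out, swap)

  truth <- data.frame(SNP = snp, gamma = gamma, alpha = alpha, maf = f,
                      causal = causal, block = layout$block_id,
                      stringsAsFactors = FALSE)
  attr(truth, "true_beta") <- config$true_beta
  list(exposure = exposure, outcome = outcome, truth = truth, config = config)
}

#' Build the LD matrix matching a simulated SNP table
#'
#' Block-diagonal squared-correlation matrix: within each configured
#' block a constant r-squared, zero across blocks, unit diagonal.  Blocks
#' are assigned to SNPs in table order, mirroring the position layout of
#' [simulate_gwas_pair()], so clumping sees consistent distances and LD.
#'
#' @param snp_table summary-statistics data.frame (only `SNP` and its
#'   order are used).
#' @param ld_blocks list of blocks, each `list(size =, r2 =)`.
#' @param seed unused placeholder (the matrix is deterministic); kept for
#'   interface symmetry with the other generators.
#' @return an `ld_matrix`.
#' @export
simulate_ld_matrix <- function(snp_table, ld_blocks = NULL, seed = NULL) {
  blocks <- normalize_ld_blocks(ld_blocks)
  n <- nrow(snp_table)
  if (sum(blocks$size) > n) {
    stop_mrkit("LD block sizes exceed the SNP count", "mrkit_config_error")
  }
  r2 <- diag(n)
  offset <- 0L
  if (nrow(blocks) > 0) {
    for (i in seq_len(nrow(blocks))) {
      idx <- offset + seq_len(blocks$size[i])
      r2[idx, idx] <- blocks$r2[i]
      diag(r2)[idx] <- 1
      offset <- offset + blocks$size[i]
    }
  }
  ld_matrix(r2, snp_ids = snp_table$SNP)
}

#' Write the synthetic pair to disk
#'
#' Emits the canonical exposure/outcome TSVs, the truth table and a YAML
#' manifest of the generating configuration.
#'
#' @param sim result of [simulate_gwas_pair()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_simulated_pair <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    exposure = file.path(dir, "exposure.tsv"),
    outcome = file.path(dir, "outcome.tsv"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "sim_config.yaml")
  )
  write_summary_stats(sim$exposure, paths[["exposure"]])
  write_summary_stats(sim$outcome, paths[["outcome"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- sim$config
  cfg$ld_blocks <- if (nrow(cfg$ld_blocks) > 0) {
    lapply(seq_len(nrow(cfg$ld_blocks)), function(i) {
      list(size = cfg$ld_blocks$size[i], r2 = cfg$ld_blocks$r2[i])
    })
  } else {
    NULL
  }
  yaml::write_yaml(unclass(cfg), paths[["manifest"]])
  invisible(paths)
}
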