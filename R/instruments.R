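# Instrument selection: p-value thresholding, LD clumping, instrument
# strength (F-statistic) and Steiger directionality filtering.

#' Construct a pairwise LD matrix
#'
#' @param r2 square symmetric matrix of pairwise squared correlations in
#'   `[0, 1]` with unit diagonal.
#' @param snp_ids SNP ids, in matrix order; defaults to `rownames(r2)`.
#' @return matrix of class `ld_matrix` with SNP ids as dimnames.
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) {
    stop_mrkit("LD matrix needs SNP ids (snp_ids or rownames)", "mrkit_config_error")
  }
  if (nrow(r2) != ncol(r2) || length(snp_ids) != nrow(r2)) {
    stop_mrkit("LD matrix must be square with one id per row", "mrkit_config_error")
  }
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop_mrkit("LD r-squared entries must lie in [0, 1]", "mrkit_config_error")
  }
  if (any(abs(r2 - t(r2)) > 1e-8)) {
    stop_mrkit("LD matrix must be symmetric", "mrkit_config_error")
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) {
    stop_mrkit("LD matrix diagonal must be 1", "mrkit_config_error")
  }
  dimnames(r2) <- list(snp_ids, snp_ids)
  class(r2) <- c("ld_matrix", class(r2))
  r2
}

#' Read / write an LD matrix as delimited text
#'
#' Square tab-separated table with SNP ids as header row and first column.
#'
#' @param path file path.
#' @return [read_ld_matrix()] an `ld_matrix`; [write_ld_matrix()] `path`.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  ld_matrix(as.matrix(raw), snp_ids = rownames(raw))
}

#' @rdname read_ld_matrix
#' @param ld `ld_matrix` to write.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(SNP = rownames(ld), unclass(ld), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter variants by association p-value
#'
#' Retains variants with `P < threshold`; the conventional locus-wide
#' significance threshold for instrument discovery is `1e-5`.
#'
#' @param records summary-statistics data.frame.
#' @param threshold p-value threshold in (0, 1].
#' @return the subset of `records` with `P < threshold`, order preserved.
#' @export
filter_by_pvalue <- function(records, threshold = 1e-5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop_mrkit("threshold must lie in (0, 1]", "mrkit_config_error")
  }
  out <- records[records$P < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

norm_chr <- function(chr) sub("^chr", "", as.character(chr), ignore.case = TRUE)

#' Greedy LD clumping
#'
#' Thins a set of variants to approximately independent index SNPs:
#' repeatedly takes the remaining variant with the smallest p-value as an
#' index SNP, then discards all remaining variants on the same chromosome
#' within `window_kb` whose squared correlation with the index is at least
#' `r2_threshold`.  Ties in p-value break lexicographically on SNP id, so
#' the result is deterministic.
#'
#' @param records summary-statistics data.frame (`SNP`, `CHR`, `POS`, `P`
#'   used).
#' @param ld `ld_matrix` covering every SNP in `records`.
#' @param r2_threshold clumping r-squared threshold (default 0.001).
#' @param window_kb clumping distance in kb (default 10,000).
#' @return the index-SNP subset of `records`, sorted by p ascending.
#' @export
ld_clump <- function(records, ld, r2_threshold = 0.001, window_kb = 10000) {
  if (r2_threshold <= 0 || r2_threshold > 1) {
    stop_mrkit("r2_threshold must lie in (0, 1]", "mrkit_config_error")
  }
  if (window_kb <= 0) stop_mrkit("window_kb must be positive", "mrkit_config_error")
  missing_ld <- setdiff(records$SNP, rownames(ld))
  if (length(missing_ld) > 0) {
    stop_mrkit(paste0("SNP(s) absent from LD matrix: ",
                      paste(missing_ld, collapse = ", ")),
               "mrkit_config_error")
  }
  if (nrow(records) == 0) return(records)

  ord <- order(records$P, records$SNP)
  pool <- records[ord, , drop = FALSE]
  pool$.chr <- norm_chr(pool$CHR)
  alive <- rep(TRUE, nrow(pool))
  index <- integer(0)
  window_bp <- window_kb * 1000
  for (i in seq_len(nrow(pool))) {
    if (!alive[i]) next
    index <- c(index, i)
    alive[i] <- FALSE
    cand <- which(alive &
                    pool$.chr == pool$.chr[i] &
                    abs(pool$POS - pool$POS[i]) <= window_bp)
    if (length(cand) > 0) {
      r2 <- ld[pool$SNP[i], pool$SNP[cand]]
      alive[cand[r2 >= r2_threshold]] <- FALSE
    }
  }
  out <- pool[index, setdiff(names(pool), ".chr"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument-strength F-statistic
#'
#' `F = R^2 (n - k - 1) / (k (1 - R^2))`, where `R^2` is the variance of
#' the exposure explained by the `k` instruments and `n` the GWAS sample
#' size.  `F < 10` conventionally flags a weak instrument.
#'
#' @param r2 variance explained, in `[0, 1)` (recycled against `n`).
#' @param n sample size, `n > k + 1`.
#' @param k number of instruments in the computation (1 for per-SNP F).
#' @return data.frame with columns `r2`, `n`, `k`, `F`, `weak`.
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0 | r2 >= 1)) {
    stop_mrkit("r2 must lie in [0, 1)", "mrkit_domain_error")
  }
  if (any(k < 1)) stop_mrkit("k must be at least 1", "mrkit_domain_error")
  if (any(n <= k + 1)) {
    stop_mrkit("n must exceed k + 1", "mrkit_domain_error")
  }
  F <- r2 * (n - k - 1) / (k * (1 - r2))
  data.frame(r2 = r2, n = n, k = k, F = F, weak = F < 10)
}

#' Per-SNP variance explained
#'
#' With an effect-allele frequency available, uses the standardized-trait
#' approximation `2 beta^2 f (1 - f)`; otherwise falls back to
#' `z^2 / (z^2 + n - 2)` with `z = beta / se`, which needs neither
#' frequency nor prevalence and behaves sensibly on the log-odds scale.
#' Vectorized; the estimator is chosen element-wise by EAF availability.
#'
#' @param beta,se per-allele effect and its standard error (`se > 0`).
#' @param n GWAS sample size (`n > 2`).
#' @param eaf effect-allele frequency, `NA`/`NULL` when unknown.
#' @return variance explained, clipped to `[0, 1)`.
#' @export
snp_r2 <- function(beta, se, n, eaf = NULL) {
  if (any(n <= 2)) stop_mrkit("n must exceed 2", "mrkit_domain_error")
  if (any(se <= 0)) stop_mrkit("se must be positive", "mrkit_domain_error")
  z2 <- (beta / se)^2
  r2 <- z2 / (z2 + n - 2)
  if (!is.null(eaf)) {
    has_f <- !is.na(eaf)
    r2[has_f] <- 2 * beta[has_f]^2 * eaf[has_f] * (1 - eaf[has_f])
  }
  pmin(pmax(r2, 0), 1 - .Machine$double.eps)
}

#' Steiger directionality filtering
#'
#' For each harmonized SNP, compares the variance explained in the
#' exposure against that in the outcome; instruments acting in the assumed
#' causal direction should explain more exposure variance.  SNPs with
#' `r2_exp > r2_out` (strict) are retained.  The per-SNP p-value is the
#' two-sample Fisher-z comparison of the implied correlations
#' `r = sqrt(r2)`:
#' `z = (atanh(r_exp) - atanh(r_out)) / sqrt(1/(n_exp-3) + 1/(n_out-3))`,
#' two-sided normal.
#'
#' @param pairs `harmonized_pairs` data.frame.
#' @return list with `retained` (the filtered pairs) and `records`
#'   (per-SNP data.frame: `SNP`, `r2_exp`, `r2_out`, `direction_ok`, `p`).
#' @export
steiger_filter <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(list(retained = pairs,
                records = data.frame(SNP = character(0), r2_exp = numeric(0),
                                     r2_out = numeric(0),
                                     direction_ok = logical(0), p = numeric(0))))
  }
  if (any(pairs$n_exp <= 3) || any(pairs$n_out <= 3)) {
    stop_mrkit("sample sizes must exceed 3 for the Fisher-z test",
               "mrkit_domain_error")
  }
  r2_exp <- snp_r2(pairs$beta_exp, pairs$se_exp, pairs$n_exp, pairs$eaf_exp)
  r2_out <- snp_r2(pairs$beta_out, pairs$se_out, pairs$n_out, pairs$eaf_out)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (pairs$n_exp - 3) + 1 / (pairs$n_out - 3))
  records <- data.frame(
    SNP = pairs$SNP, r2_exp = r2_exp, r2_out = r2_out,
    direction_ok = r2_exp > r2_out,
    p = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE
  )
  retained <- pairs[records$direction_ok, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, records = records)
}
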