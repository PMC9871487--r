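# Reading, validating and harmonizing GWAS summary-statistics tables.
#
# The canonical in-memory representation of a summary-statistics table is a
# data.frame with columns SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N —
# one row per variant, one table per trait.

CANONICAL_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
REQUIRED_COLS <- setdiff(CANONICAL_COLS, "EAF")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Validate a summary-statistics table
#'
#' Checks every row of a table of per-SNP associations against the
#' invariants of the format: single-base distinct alleles, positive SE,
#' p-values in (0, 1], effect-allele frequency in (0, 1) when present.
#'
#' @param x data.frame with the canonical columns `SNP`, `CHR`, `POS`,
#'   `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N` (`EAF` may be `NA`).
#' @return `x`, invisibly, with alleles upper-cased; errors describe the
#'   offending row.
#' @export
validate_summary_stats <- function(x) {
  missing_cols <- setdiff(REQUIRED_COLS, names(x))
  if (length(missing_cols) > 0) {
    stop_mrkit(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      "mrkit_config_error"
    )
  }
  if (!"EAF" %in% names(x)) x$EAF <- NA_real_
  if (nrow(x) == 0) {
    stop_mrkit("summary-statistics table is empty", "mrkit_empty_input")
  }
  x$EA <- toupper(as.character(x$EA))
  x$OA <- toupper(as.character(x$OA))
  x$CHR <- as.character(x$CHR)

  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      stop_mrkit(
        sprintf("row %d: %s", idx[1], what),
        "mrkit_validation_error"
      )
    }
  }
  bad_row(!x$EA %in% VALID_ALLELES, "effect allele must be a single base (A/C/G/T)")
  bad_row(!x$OA %in% VALID_ALLELES, "other allele must be a single base (A/C/G/T)")
  bad_row(x$EA == x$OA, "effect and other allele must differ")
  bad_row(!is.finite(x$SE) | x$SE <= 0, "SE must be a positive real")
  bad_row(!is.finite(x$P) | x$P <= 0 | x$P > 1, "p-value must lie in (0, 1]")
  bad_row(!is.finite(x$N) | x$N <= 0, "sample size must be positive")
  bad_row(!is.finite(x$BETA), "beta must be finite")
  bad_row(!is.finite(x$POS) | x$POS < 1, "position must be a positive 1-based integer")
  eaf_bad <- !is.na(x$EAF) & (x$EAF <= 0 | x$EAF >= 1)
  bad_row(eaf_bad, "EAF must lie strictly in (0, 1) when present")
  invisible(x[, CANONICAL_COLS])
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file of per-SNP associations, renames columns to
#' the canonical scheme via `column_map`, and validates every row.  Row
#' order is preserved, so a write/read round trip is the identity.
#'
#' @param path path to a delimited text file with a header.
#' @param column_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(SNP = "rsids", BETA = "beta", ...)`.
#'   Canonical names already present in the file need not be mapped; `EAF`
#'   is optional.
#' @param sep field separator (default tab).
#' @return data.frame with columns `SNP`, `CHR`, `POS`, `EA`, `OA`, `EAF`,
#'   `BETA`, `SE`, `P`, `N`.
#' @export
read_summary_stats <- function(path, column_map = NULL, sep = "\t") {
  if (!file.exists(path)) {
    stop_mrkit(paste0("file not found: ", path), "mrkit_config_error")
  }
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src) > 0) {
      stop_mrkit(
        paste0("column_map refers to absent column(s): ",
               paste(missing_src, collapse = ", ")),
        "mrkit_config_error"
      )
    }
    for (canon in names(column_map)) {
      raw[[canon]] <- raw[[column_map[[canon]]]]
    }
  }
  validate_summary_stats(raw)
}

#' Write a GWAS summary-statistics table
#'
#' Tab-separated counterpart of [read_summary_stats()]; `read(write(x))`
#' reproduces `x` field-by-field.
#'
#' @param x validated summary-statistics data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  x <- validate_summary_stats(x)
  out <- x
  for (col in c("EAF", "BETA", "SE", "P")) {
    # 17 significant digits: doubles survive the text round trip exactly
    out[[col]] <- ifelse(is.na(x[[col]]), "NA", sprintf("%.17g", x[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

complement_allele <- function(a) {
  c(A = "T", C = "G", G = "C", T = "A")[a]
}

#' Harmonize an exposure/outcome summary-statistics pair
#'
#' Aligns the outcome associations onto the exposure's effect alleles so
#' that every retained SNP carries a (beta_exp, beta_out) pair referring to
#' the same allele.  Outcome records whose alleles are swapped relative to
#' the exposure have their beta negated and EAF replaced by 1 - EAF;
#' records on the opposite strand are matched after complementing the
#' outcome alleles.  Palindromic (A/T, C/G) SNPs — whose strand cannot be
#' resolved from alleles alone — are dropped, as are SNPs whose allele
#' pairs cannot be reconciled at all.
#'
#' @param exposure,outcome validated summary-statistics data.frames with
#'   unique SNP ids.
#' @param palindrome_policy currently only `"drop"`.
#' @return data.frame of class `harmonized_pairs`, sorted by SNP id, with
#'   columns `SNP`, `CHR`, `POS`, `EA`, `OA`, `beta_exp`, `se_exp`,
#'   `pval_exp`, `eaf_exp`, `n_exp`, `beta_out`, `se_out`, `pval_out`,
#'   `eaf_out`, `n_out`, `action`.  The attribute `"harmonization_log"`
#'   records per-reason drop counts and the dropped SNP ids.
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_policy = c("drop")) {
  palindrome_policy <- match.arg(palindrome_policy)
  exposure <- validate_summary_stats(exposure)
  outcome <- validate_summary_stats(outcome)
  for (nm in c("exposure", "outcome")) {
    tab <- if (nm == "exposure") exposure else outcome
    dup <- tab$SNP[duplicated(tab$SNP)]
    if (length(dup) > 0) {
      stop_mrkit(
        sprintf("duplicate SNP id(s) in %s: %s", nm,
                paste(unique(dup), collapse = ", ")),
        "mrkit_validation_error"
      )
    }
  }

  common <- intersect(exposure$SNP, outcome$SNP)
  log <- list(
    n_exposure = nrow(exposure), n_outcome = nrow(outcome),
    n_common = length(common), dropped = data.frame(
      SNP = character(0), reason = character(0), stringsAsFactors = FALSE
    )
  )
  drop <- function(snp, reason) {
    log$dropped <<- rbind(log$dropped,
                          data.frame(SNP = snp, reason = reason,
                                     stringsAsFactors = FALSE))
  }

  e <- exposure[match(common, exposure$SNP), , drop = FALSE]
  o <- outcome[match(common, outcome$SNP), , drop = FALSE]

  keep <- logical(length(common))
  flip <- logical(length(common))
  action <- character(length(common))
  for (i in seq_along(common)) {
    if (is_palindromic(e$EA[i], e$OA[i]) || is_palindromic(o$EA[i], o$OA[i])) {
      drop(common[i], "palindromic")
      next
    }
    direct <- o$EA[i] == e$EA[i] && o$OA[i] == e$OA[i]
    swapped <- o$EA[i] == e$OA[i] && o$OA[i] == e$EA[i]
    cEA <- complement_allele(o$EA[i]); cOA <- complement_allele(o$OA[i])
    comp <- cEA == e$EA[i] && cOA == e$OA[i]
    comp_swapped <- cEA == e$OA[i] && cOA == e$EA[i]
    # both a same-strand and an opposite-strand reading fit: unresolvable
    if ((direct || swapped) && (comp || comp_swapped)) {
      drop(common[i], "ambiguous")
      next
    }
    if (direct) {
      keep[i] <- TRUE; action[i] <- "direct"
    } else if (swapped) {
      keep[i] <- TRUE; flip[i] <- TRUE; action[i] <- "swap"
    } else if (comp) {
      keep[i] <- TRUE; action[i] <- "complement"
    } else if (comp_swapped) {
      keep[i] <- TRUE; flip[i] <- TRUE; action[i] <- "complement_swap"
    } else {
      drop(common[i], "irreconcilable")
    }
  }

  out <- data.frame(
    SNP = common, CHR = e$CHR, POS = e$POS, EA = e$EA, OA = e$OA,
    beta_exp = e$BETA, se_exp = e$SE, pval_exp = e$P, eaf_exp = e$EAF,
    n_exp = e$N,
    beta_out = ifelse(flip, -o$BETA, o$BETA),
    se_out = o$SE, pval_out = o$P,
    eaf_out = ifelse(flip, 1 - o$EAF, o$EAF),
    n_out = o$N,
    action = action,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  out <- out[order(out$SNP), , drop = FALSE]
  rownames(out) <- NULL

  log$n_palindromic <- sum(log$dropped$reason == "palindromic")
  log$n_ambiguous <- sum(log$dropped$reason == "ambiguous")
  log$n_irreconcilable <- sum(log$dropped$reason == "irreconcilable")
  log$n_retained <- nrow(out)
  if (nrow(out) == 0) {
    warning("no SNPs retained after harmonization", call. = FALSE)
  }
  attr(out, "harmonization_log") <- log
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}

#' @export
print.harmonized_pairs <- function(x, ...) {
  log <- attr(x, "harmonization_log")
  cat(sprintf(
    "Harmonized exposure/outcome pair: %d SNPs retained of %d common\n",
    nrow(x), log$n_common %||% nrow(x)
  ))
  if (!is.null(log) && nrow(log$dropped) > 0) {
    tab <- table(log$dropped$reason)
    cat("Dropped:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  print(as.data.frame(x), ...)
  invisible(x)
}
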