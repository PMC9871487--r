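# Study orchestration: run the full two-sample MR pipeline over a grid of
# exposure/outcome pairs, staged as discovery and replication, and emit
# report tables (per-method p-values plus the sensitivity battery,
# mirroring the layout used in published MR studies).

#' Study configuration
#'
#' @param exposures named list; each element a summary-statistics
#'   data.frame or a path to a canonical TSV.
#' @param outcomes named list; each element a list with `data` (data.frame
#'   or path), `stage` (`"discovery"` or `"replicated"`) and optionally
#'   `trait` (disease label linking a discovery outcome with its
#'   replication counterpart; defaults to the element name).
#' @param ld LD information for clumping: an `ld_matrix`, a path to one,
#'   a character vector of pre-clumped index SNP ids (bypass mode), or
#'   `NULL` to skip clumping (instruments assumed independent).
#' @param p_iv instrument p-value threshold (default `1e-5`, locus-wide
#'   significance).
#' @param clump_r2 LD clumping r-squared threshold (default 0.001).
#' @param clump_kb clumping distance in kb (default 10,000).
#' @param alpha suggestive-significance level (default 0.05).
#' @param methods estimators to run on multi-SNP sets; any of `"ivw"`,
#'   `"egger"`, `"weighted_median"`, `"mle"`, `"raps"`.
#' @param steiger apply Steiger directionality filtering (default `TRUE`).
#' @param sensitivity run the heterogeneity/pleiotropy/outlier battery
#'   (default `TRUE`).
#' @param n_boot weighted-median bootstrap replicates.
#' @param presso_n_sim MR-PRESSO simulation draws.
#' @param seed master seed; per-pair sub-seeds are derived from it.
#' @return list of class `study_config`.
#' @export
study_config <- function(exposures, outcomes, ld = NULL,
                         p_iv = 1e-5, clump_r2 = 0.001, clump_kb = 10000,
                         alpha = 0.05,
                         methods = c("ivw", "egger", "weighted_median",
                                     "mle", "raps"),
                         steiger = TRUE, sensitivity = TRUE,
                         n_boot = 1000, presso_n_sim = 1000, seed = 1) {
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    stop_mrkit("exposures must be a named list", "mrkit_config_error")
  }
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    stop_mrkit("outcomes must be a named list", "mrkit_config_error")
  }
  outcomes <- lapply(seq_along(outcomes), function(i) {
    o <- outcomes[[i]]
    if (is.data.frame(o) || is.character(o)) o <- list(data = o)
    o$stage <- match.arg(o$stage %||% "discovery", c("discovery", "replicated"))
    o$trait <- o$trait %||% names(outcomes)[i]
    o
  }) |> stats::setNames(names(outcomes))
  methods <- match.arg(methods, c("ivw", "egger", "weighted_median",
                                  "mle", "raps"), several.ok = TRUE)
  if (alpha <= 0 || alpha > 1) {
    stop_mrkit("alpha must lie in (0, 1]", "mrkit_config_error")
  }
  structure(list(exposures = exposures, outcomes = outcomes, ld = ld,
                 p_iv = p_iv, clump_r2 = clump_r2, clump_kb = clump_kb,
                 alpha = alpha, methods = methods, steiger = steiger,
                 sensitivity = sensitivity, n_boot = n_boot,
                 presso_n_sim = presso_n_sim, seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Keys mirror the [study_config()] arguments: `exposures` and `outcomes`
#' as lists of `{name, path, stage, trait}` entries, `ld` as
#' `{matrix: path}` or `{clumps: path}` (one index SNP id per line), a
#' `thresholds` block (`p_iv`, `clump_r2`, `clump_kb`, `alpha`),
#' `methods`, and `seed`.
#'
#' @param path YAML file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  exposures <- stats::setNames(
    lapply(y$exposures, function(e) e$path),
    vapply(y$exposures, function(e) e$name, character(1))
  )
  outcomes <- stats::setNames(
    lapply(y$outcomes, function(o) {
      list(data = o$path, stage = o$stage %||% "discovery", trait = o$trait)
    }),
    vapply(y$outcomes, function(o) o$name, character(1))
  )
  ld <- NULL
  if (!is.null(y$ld$matrix)) ld <- read_ld_matrix(y$ld$matrix)
  if (!is.null(y$ld$clumps)) ld <- readLines(y$ld$clumps)
  th <- y$thresholds %||% list()
  study_config(
    exposures = exposures, outcomes = outcomes, ld = ld,
    p_iv = th$p_iv %||% 1e-5, clump_r2 = th$clump_r2 %||% 0.001,
    clump_kb = th$clump_kb %||% 10000, alpha = th$alpha %||% 0.05,
    methods = as.character(unlist(y$methods %||%
      c("ivw", "egger", "weighted_median", "mle", "raps"))),
    steiger = y$steiger %||% TRUE, sensitivity = y$sensitivity %||% TRUE,
    n_boot = y$n_boot %||% 1000, presso_n_sim = y$presso_n_sim %||% 1000,
    seed = y$seed %||% 1
  )
}

load_table <- function(x) {
  if (is.character(x)) read_summary_stats(x) else validate_summary_stats(x)
}

try_cell <- function(expr) {
  tryCatch(list(value = expr, error = NA_character_),
           mrkit_error = function(e) list(value = NULL,
                                          error = conditionMessage(e)))
}

# Analyze one exposure/outcome pair end-to-end; returns the per-pair
# detail record consumed by the report builder.
analyze_pair <- function(exposure, outcome, config, pair_seed) {
  counts <- c(total = nrow(exposure))
  iv <- filter_by_pvalue(exposure, config$p_iv)
  counts["p_filter"] <- nrow(iv)

  if (!is.null(config$ld) && nrow(iv) > 0) {
    if (inherits(config$ld, "ld_matrix")) {
      iv <- ld_clump(iv, config$ld, config$clump_r2, config$clump_kb)
    } else if (is.character(config$ld) && length(config$ld) == 1 &&
               file.exists(config$ld)) {
      iv <- ld_clump(iv, read_ld_matrix(config$ld), config$clump_r2,
                     config$clump_kb)
    } else {
      iv <- iv[iv$SNP %in% config$ld, , drop = FALSE]   # pre-clumped ids
    }
  }
  counts["clump"] <- nrow(iv)

  pairs <- if (nrow(iv) > 0) {
    suppressWarnings(harmonize_pair(iv, outcome))
  } else {
    NULL
  }
  counts["harmonized"] <- if (is.null(pairs)) 0L else nrow(pairs)

  steiger_records <- NULL
  if (config$steiger && !is.null(pairs) && nrow(pairs) > 0) {
    st <- steiger_filter(pairs)
    pairs <- st$retained
    steiger_records <- st$records
  }
  counts["steiger"] <- if (is.null(pairs)) 0L else nrow(pairs)
  stopifnot(all(diff(counts) <= 0))   # filter chain only ever shrinks

  if (is.null(pairs) || nrow(pairs) == 0) {
    return(list(counts = counts, no_instruments = TRUE, estimates = list(),
                sensitivity = list(), strength = NULL,
                steiger = steiger_records, loo = NULL))
  }

  r2 <- snp_r2(pairs$beta_exp, pairs$se_exp, pairs$n_exp, pairs$eaf_exp)
  strength <- f_statistic(r2, pairs$n_exp, k = 1)
  strength$SNP <- pairs$SNP
  set_F <- if (nrow(pairs) + 1 < min(pairs$n_exp)) {
    f_statistic(min(sum(r2), 1 - 1e-12), min(pairs$n_exp), k = nrow(pairs))$F
  } else {
    NA_real_
  }

  J <- nrow(pairs)
  estimates <- list()
  if (J == 1) {
    estimates$wald_ratio <- try_cell(wald_ratio(pairs))
  } else {
    runners <- list(
      ivw = function() ivw(pairs),
      egger = function() mr_egger(pairs),
      weighted_median = function() weighted_median(pairs, config$n_boot,
                                                   seed = derive_seed(pair_seed, 1)),
      mle = function() max_likelihood(pairs),
      raps = function() mr_raps(pairs)
    )
    for (m in config$methods) estimates[[m]] <- try_cell(runners[[m]]())
  }

  sens <- list()
  loo <- NULL
  if (config$sensitivity && J >= 2) {
    sens$q_ivw <- try_cell(cochran_q(pairs, "ivw"))
    sens$q_egger <- try_cell(cochran_q(pairs, "egger"))
    sens$egger_intercept <- try_cell(egger_intercept_test(pairs))
    sens$presso <- try_cell(mr_presso(pairs, n_sim = config$presso_n_sim,
                                      seed = derive_seed(pair_seed, 2)))
    loo_cell <- try_cell(leave_one_out(pairs))
    loo <- loo_cell$value
  }

  list(counts = counts, no_instruments = FALSE, estimates = estimates,
       sensitivity = sens, strength = strength, set_F = set_F,
       steiger = steiger_records, pairs = pairs, loo = loo)
}

cell_p <- function(cell) {
  if (is.null(cell) || is.null(cell$value)) NA_real_ else cell$value$pval
}
cell_beta <- function(cell) {
  if (is.null(cell) || is.null(cell$value)) NA_real_ else cell$value$beta
}

#' Run a two-sample MR study
#'
#' Executes, for every exposure x outcome pair: read, p-value filter, LD
#' clumping, harmonization (palindromic SNPs dropped), Steiger filtering,
#' instrument-strength F-statistics, the configured causal estimators,
#' the sensitivity battery, and the odds-ratio transform.  Pairs with no
#' surviving instruments yield an explicit "no instruments" row rather
#' than an error; estimator failures are recorded per cell.  A
#' replication-stage row is flagged `replicated` when the discovery pair
#' for the same exposure and trait is suggestive and the replication
#' estimate is suggestive with the same sign.  Deterministic given the
#' config seed.
#'
#' @param config a `study_config`.
#' @param out_dir optional directory for `report.tsv`, `estimates.tsv`,
#'   `loo.tsv` and `log.txt`.
#' @return list of class `mr_report`: `report` (one row per
#'   exposure x outcome x stage), `estimates` (tidy per-method table),
#'   `loo` (leave-one-out series), `details` (per-pair records).
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  exposures <- lapply(config$exposures, load_table)
  outcomes <- lapply(config$outcomes, function(o) {
    o$data <- load_table(o$data)
    o
  })

  rows <- list()
  est_rows <- list()
  loo_rows <- list()
  details <- list()
  log_lines <- character(0)
  pair_idx <- 0L
  n_pairs <- length(exposures) * length(outcomes)

  for (en in names(exposures)) {
    for (on in names(outcomes)) {
      pair_idx <- pair_idx + 1L
      o <- outcomes[[on]]
      det <- analyze_pair(exposures[[en]], o$data, config,
                          pair_seed = derive_seed(config$seed, pair_idx))
      details[[paste(en, on, sep = ".")]] <- det
      log_lines <- c(log_lines, sprintf(
        "%s x %s [%s]: SNPs %s", en, on, o$stage,
        paste(sprintf("%s=%d", names(det$counts), det$counts), collapse = " ")
      ))

      ivw_cell <- det$estimates$ivw %||% det$estimates$wald_ratio
      p_ivw <- cell_p(ivw_cell)
      suggestive <- !is.na(p_ivw) && p_ivw < config$alpha
      row <- data.frame(
        exposure = en, outcome = on, trait = o$trait, stage = o$stage,
        n_total = det$counts[["total"]], n_p_filter = det$counts[["p_filter"]],
        n_clump = det$counts[["clump"]],
        n_harmonized = det$counts[["harmonized"]],
        n_steiger = det$counts[["steiger"]],
        F_min = if (is.null(det$strength)) NA_real_ else min(det$strength$F),
        F_max = if (is.null(det$strength)) NA_real_ else max(det$strength$F),
        beta_IVW = cell_beta(ivw_cell),
        P_IVW = p_ivw,
        P_Egger = cell_p(det$estimates$egger),
        P_WM = cell_p(det$estimates$weighted_median),
        P_MLE = cell_p(det$estimates$mle),
        P_RAPS = cell_p(det$estimates$raps),
        P_Q_IVW = cell_p(det$sensitivity$q_ivw),
        P_Q_Egger = cell_p(det$sensitivity$q_egger),
        P_Egger_intercept = if (is.null(det$sensitivity$egger_intercept$value))
          NA_real_ else det$sensitivity$egger_intercept$value$pval,
        P_PRESSO_global = if (is.null(det$sensitivity$presso$value))
          NA_real_ else det$sensitivity$presso$value$global_p,
        no_instruments = det$no_instruments,
        suggestive = suggestive,
        P_IVW_bonferroni = pmin(1, p_ivw * n_pairs),
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- row

      for (m in names(det$estimates)) {
        cell <- det$estimates[[m]]
        if (!is.null(cell$value)) {
          tab <- mr_estimates_table(to_odds_ratio(cell$value))
          tab$exposure <- en; tab$outcome <- on; tab$stage <- o$stage
          est_rows[[length(est_rows) + 1L]] <- tab
        } else {
          log_lines <- c(log_lines, sprintf("  %s failed: %s", m, cell$error))
        }
      }
      if (!is.null(det$loo)) {
        lo <- det$loo
        lo$exposure <- en; lo$outcome <- on
        loo_rows[[length(loo_rows) + 1L]] <- as.data.frame(lo)
      }
    }
  }

  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  # replication verdict: suggestive in both stages with concordant sign
  report$replicated <- NA
  repl <- which(report$stage == "replicated")
  for (i in repl) {
    disc <- which(report$stage == "discovery" &
                    report$exposure == report$exposure[i] &
                    report$trait == report$trait[i])
    if (length(disc) > 0) {
      ok <- any(report$suggestive[disc] & report$suggestive[i] &
                  sign(report$beta_IVW[disc]) == sign(report$beta_IVW[i]),
                na.rm = TRUE)
      report$replicated[i] <- ok
    }
  }

  out <- structure(list(
    report = report,
    estimates = if (length(est_rows) > 0) do.call(rbind, est_rows) else NULL,
    loo = if (length(loo_rows) > 0) do.call(rbind, loo_rows) else NULL,
    details = details, config = config, log = log_lines
  ), class = "mr_report")

  if (!is.null(out_dir)) write_mr_report(out, out_dir)
  out
}

#' Write an MR study report to disk
#'
#' Emits `report.tsv` (one row per exposure x outcome x stage),
#' `estimates.tsv` (tidy per-method estimates with OR columns),
#' `loo.tsv` and `log.txt` (per-filter SNP counts).  Asserts the
#' filter-count monotonicity invariant before writing.
#'
#' @param x an `mr_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_mr_report <- function(x, dir) {
  stopifnot(inherits(x, "mr_report"))
  counts <- x$report[, c("n_total", "n_p_filter", "n_clump", "n_harmonized",
                         "n_steiger")]
  stopifnot(all(apply(counts, 1, function(v) all(diff(v) <= 0))))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  wt(x$report, "report.tsv")
  wt(x$estimates, "estimates.tsv")
  wt(x$loo, "loo.tsv")
  writeLines(x$log, file.path(dir, "log.txt"))
  invisible(dir)
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR study report: %d exposure x outcome rows\n", nrow(x$report)))
  cols <- c("exposure", "outcome", "stage", "n_steiger", "P_IVW",
            "suggestive", "replicated")
  print(x$report[, intersect(cols, names(x$report))], ...)
  invisible(x)
}
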