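# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded routines (bootstrap,
#' MR-PRESSO simulations, the synthetic generator) do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic sub-stream seed from a master seed.  Uses a
# Lehmer step so distinct (seed, stream) pairs map to distinct 31-bit
# seeds; adding SNPs or components never reshuffles earlier draws.
derive_seed <- function(seed, stream) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  for (i in seq_len(stream)) {
    s <- (s * 48271) %% m
  }
  as.integer(s)
}

# Two-sided normal p-value from an estimate and its SE.
pval_norm <- function(beta, se) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mrkit <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mrkit_error")))
}
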