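# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global random-number state set from \code{seed}
#' and restores the previous state afterwards, so no function in the package
#' leaves a footprint on the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a parent seed, kept inside the
# 32-bit integer range.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 97 + k * 1009) %% 2147483587 + 1
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Two-sided normal p-value for an estimate/se pair.
z_pvalue <- function(estimate, se) {
  2 * stats::pnorm(-abs(estimate / se))
}

stop_mrflow <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "mrflow_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
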