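#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor lm logLik median p.adjust pchisq pexp pt qnorm
#'   rbinom rexp rlnorm rnbinom rnorm runif sd setNames var
#' @importFrom utils read.delim write.table
NULL

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards.  Keeps every stochastic operation seed-local so
# no function disturbs global random state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sub-seed derivation: distinct stream per stage, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("%s must lie in [0, 1]", what)
  invisible(x)
}
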