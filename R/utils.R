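# Internal helpers: seed management, validation, logging.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations do not
#' perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seed for a named operation. Keeps all derived
# seeds below 2^31 so they remain valid R integers.
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) * 48271 + as.double(offset) * 104729) %% 2147483629
  as.integer(s)
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tw_log <- function(..., verbose = getOption("twinprs.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[twinprs] ", sprintf(...))
  invisible(NULL)
}
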