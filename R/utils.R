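# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so seeded package functions do not perturb user code.
#'
#' @param seed integer seed, or NULL to run with the current RNG state.
#' @param code expression to evaluate.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a master seed. Offsets keep stage
# streams independent; modulus keeps the result a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
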