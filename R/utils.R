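#' @keywords internal
"_PACKAGE"

## Seed plumbing ---------------------------------------------------------

#' Derive a reproducible child seed from a root seed and a label
#'
#' All stochastic steps in the package draw from streams derived
#' deterministically from one root seed, so that e.g. adding a chromosome to a
#' simulated genome does not shift the draws used for the other chromosomes.
#' The derivation is a small polynomial string hash folded with the root seed,
#' kept strictly below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% m
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so package internals never disturb the
#' caller's RNG state.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Logging ---------------------------------------------------------------

pc_log <- function(module, fmt, ...) {
  message(sprintf("[pointcen:%s] %s", module, sprintf(fmt, ...)))
}

## Small validators ------------------------------------------------------

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}
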