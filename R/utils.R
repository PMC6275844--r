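# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `expr`, and restores the
#' previous state on exit, so seeded package operations never perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a stream-specific sub-seed from a master seed; kept < 2^31.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 1103515245 + 12345 * stream) %% 2147483647
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

oct_verbose <- function() isTRUE(getOption("octaline.verbose", FALSE))

oct_log <- function(fmt, ...) {
  if (oct_verbose()) message(sprintf("[octaline %s] ", format(Sys.time(), "%H:%M:%S")), sprintf(fmt, ...))
}

# Circular (wrap-aware) column indices, 1-based.
wrap_idx <- function(i, n) ((i - 1L) %% n) + 1L
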