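#' @keywords internal
"_PACKAGE"

#' @useDynLib chromocast, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats ks.test fisher.test t.test rpois rbinom rnorm runif
#'   median mad sd dbinom dnorm dhyper setNames
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. seed = NULL evaluates in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## Draw a recordable seed when the caller did not supply one, so that every
## stochastic operation can be replayed bit-identically from its event log.
draw_seed <- function(seed) {
  if (is.null(seed)) sample.int(.Machine$integer.max, 1L) else as.integer(seed)
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", name), call. = FALSE)
  invisible(as.numeric(x))
}
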