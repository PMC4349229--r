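#' @importFrom stats rbinom rexp rpois runif sd var setNames phyper qnorm
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library calls never disturb the
#' caller's RNG stream. All stochastic entry points funnel through this.
#'
#' @param seed single integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

#' Derive a stage seed from a master seed
#'
#' Deterministic splitting scheme: stage k of master seed s maps to
#' `(s * 48271 + k) mod (2^31 - 1)`, a Lehmer step, so independent stages
#' never share a stream and every derived seed stays a valid 32-bit integer.
#'
#' @param seed master integer seed
#' @param k non-negative integer stage index
#' @return a single integer in `[1, 2^31 - 2]`
#' @export
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(k)
  as.integer(s %% 2147483647 + 1)
}

choose2 <- function(n) n * (n - 1) / 2

stop_if_not_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(TRUE)
}
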