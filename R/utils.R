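# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never clobbers the
#' caller's RNG stream. All stochastic operations in the package route their
#' seeds through this helper.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_cpifuse <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cpifuse_error")))
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) stats::plogis(x)

# clamp probabilities away from {0,1} for log-loss
clamp01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)
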