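#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef median pchisq phyper pnorm pt qlogis quantile
#'   rbinom rexp rnbinom rnorm runif sd var glm binomial fisher.test
#'   p.adjust setNames complete.cases plogis rweibull
#' @importFrom utils head read.delim write.table
NULL

# Run `expr` under an explicit seed without touching global RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  assert_scalar_number(x, name, min = min)
  if (x != round(x)) {
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
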