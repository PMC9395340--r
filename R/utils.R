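#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm sd cor lm coef residuals
#' @importFrom utils read.csv write.csv
NULL

## round half up: base round() is round-half-even, which would report 40.5 as 40
roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

## classed conditions so callers (and the CLI) can distinguish bad input from
## an algorithmic failure such as a non-positive slope
pfStop <- function(stage, msg, class) {
  stop(structure(
    class = c(class, "pulmoflow_error", "error", "condition"),
    list(message = sprintf("[%s] %s", stage, msg), call = sys.call(-1))
  ))
}

pfInputError <- function(stage, msg) pfStop(stage, msg, "pulmoflow_input_error")
pfAlgorithmError <- function(stage, msg) pfStop(stage, msg, "pulmoflow_algorithm_error")

## run an expression with a private RNG stream, leaving the caller's untouched
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
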