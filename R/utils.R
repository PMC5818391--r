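# Internal helpers: classed conditions, seeded RNG scoping, small numerics.

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("nemaquant_invalid_argument",
                                     "nemaquant_error")))
}

stop_coverage <- function(msg) {
  stop(errorCondition(msg, class = c("nemaquant_coverage_error",
                                     "nemaquant_error")))
}

stop_geometry <- function(msg) {
  stop(errorCondition(msg, class = c("nemaquant_geometry_error",
                                     "nemaquant_error")))
}

stop_infeasible <- function(msg) {
  stop(errorCondition(msg, class = c("nemaquant_infeasible",
                                     "nemaquant_error")))
}

is_infeasible_error <- function(e) inherits(e, "nemaquant_infeasible")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. seed = NULL runs expr with the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Center value of a uniform unit ball of radius R convolved with an
# isotropic Gaussian of width sigma (closed form; used as an oracle).
ball_blur_center <- function(R, sigma) {
  if (sigma <= 0) return(1)
  u <- R / sigma
  erf(u / sqrt(2)) - sqrt(2 / pi) * u * exp(-u^2 / 2)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
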