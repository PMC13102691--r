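#' @importFrom stats cor quantile median sd var rnorm runif predict coef
#'   setNames p.adjust pnorm lm resid fitted anova as.formula complete.cases
#' @importFrom rlang .data
#' @importFrom utils head tail
NULL

#' Derive a child seed from a master seed and a stage counter
#'
#' All generators in the package fan out from a single master seed through
#' this counter-based splitter, so that each pipeline stage consumes an
#' independent, reproducible stream. Results stay below 2^31 and are valid
#' arguments to [set.seed()].
#'
#' @param master integer master seed.
#' @param counter non-negative integer stream index (stage or scan counter).
#' @return a single integer seed.
#' @export
#' @examples
#' split_seed(1, 0)
#' split_seed(1, 1)
split_seed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  # affine congruential mix; doubles are exact well beyond these magnitudes
  m <- 2147483629
  s <- (abs(master) %% m) * 48271 + (counter %% m) * 69621 + 1
  as.integer(s %% m)
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant vector", call. = FALSE)
  (x - mean(x)) / s
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_param("%s must be a numeric matrix", name)
  if (any(!is.finite(x)))
    stop_param("%s contains non-finite values", name)
  invisible(x)
}

#' Sign convention for a loading vector: largest-magnitude entry positive
#' @noRd
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}
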