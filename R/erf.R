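#' Error function and relatives
#'
#' The error function, its complement and the inverse complement, expressed
#' through the normal distribution functions of \pkg{stats}. Every normal
#' cumulative-distribution computation in the package routes through this
#' primitive pair, so all closed-form expressions for sensitivity,
#' specificity and the ROC curve agree with their error-function forms to
#' machine precision.
#'
#' `erf(x) = 2/sqrt(pi) * integral of exp(-t^2) from 0 to x`, and
#' `erfc(x) = 1 - erf(x)`. `erfcinv` is the inverse of `erfc` on (0, 2).
#'
#' @param x numeric vector.
#' @param y numeric vector in (0, 2) for `erfcinv`.
#' @return numeric vector of the same length as the input.
#' @examples
#' erf(0)            # 0
#' erfc(0)           # 1
#' erfcinv(erfc(1))  # 1
#' @export
erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

#' @rdname erf
#' @export
erfc <- function(x) 2 * stats::pnorm(sqrt(2) * x, lower.tail = FALSE)

#' @rdname erf
#' @export
erfcinv <- function(y) stats::qnorm(y / 2, lower.tail = FALSE) / sqrt(2)

# Normal CDF and quantile in terms of the primitive pair; used internally so
# that the package has a single normal-probability code path.
.norm_cdf <- function(x, mean, sd) 0.5 * erfc((mean - x) / (sqrt(2) * sd))

.norm_sf <- function(x, mean, sd) 0.5 * erfc((x - mean) / (sqrt(2) * sd))

.norm_quantile <- function(p, mean, sd) mean - sqrt(2) * sd * erfcinv(2 * p)

# upper-tail quantile: x with survival probability p; avoids computing 1 - p
.norm_quantile_upper <- function(p, mean, sd) mean + sqrt(2) * sd * erfcinv(2 * p)
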