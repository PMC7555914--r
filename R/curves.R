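#' Binormal ROC curve
#'
#' The receiver operating characteristic of a test under the binormal model,
#' expressed directly as a function of the false-positive fraction
#' `t = 1 - Sp`:
#' \deqn{roc(t) = S(S^{-1}(t;\ \mu_{\bar D}, \sigma_{\bar D,eff});\
#'   \mu_D, \sigma_{D,eff})}
#' where `S` is the normal survival function and the effective SDs combine
#' the population spread with the measurement uncertainty `u`. Equivalently,
#' `roc(1 - specificity(d)) = sensitivity(d)` for every threshold `d`.
#' The endpoints `t = 0` and `t = 1` return the exact limits 0 and 1 rather
#' than evaluating the quantile function at its singularities.
#'
#' @param t false-positive fraction(s) in `[0, 1]`.
#' @param model a [test_model()].
#' @return true-positive fraction(s).
#' @examples
#' tm <- test_model(population_pair(2.99, 0.75, 0, 1, 0.067), 0.023)
#' roc(1 - specificity(2.26, tm), tm)  # = sensitivity(2.26, tm)
#' @export
roc <- function(t, model) {
  stopifnot(inherits(model, "test_model"), is.numeric(t))
  if (any(t < 0 | t > 1)) stop("t (false-positive fraction) must lie in [0, 1]")
  out <- numeric(length(t))
  inner <- t > 0 & t < 1
  # threshold with 1 - Sp = t, then Se there
  d <- .norm_quantile(1 - t[inner], model$pop$mu_nd, .sigma_nd_eff(model))
  out[inner] <- sensitivity(d, model)
  out[t == 0] <- 0
  out[t == 1] <- 1
  out
}

#' Area under and over the binormal ROC curve
#'
#' Closed form for the area under the ROC curve:
#' \deqn{AUC = \Phi\left(\frac{\mu_D - \mu_{\bar D}}
#'   {\sqrt{\sigma_{\bar D}^2 + \sigma_D^2 + 2u^2}}\right)}
#' with \eqn{\Phi} the standard normal CDF. The measurement uncertainty
#' enters twice under the square root because it inflates both populations'
#' observed spread. `aoc` is the complementary area over the curve,
#' `1 - auc`.
#'
#' @param model a [test_model()].
#' @return area in `[0, 1]`.
#' @examples
#' auc(test_model(population_pair(2.99, 0.75, 0, 1, 0.067), 0.023))  # ~0.9916
#' @export
auc <- function(model) {
  stopifnot(inherits(model, "test_model"))
  p <- model$pop
  .norm_cdf(p$mu_d - p$mu_nd, 0, sqrt(p$sigma_nd^2 + p$sigma_d^2 + 2 * model$u^2))
}

#' @rdname auc
#' @export
aoc <- function(model) 1 - auc(model)

#' Euclidean distance of a ROC curve point from perfect accuracy
#'
#' Distance of the curve point `(t, roc(t))` from the corner `(0, 1)`:
#' `sqrt(t^2 + (1 - roc(t))^2)`. At the threshold generating `t` this equals
#' the `ed` column of [dam_table()].
#'
#' @inheritParams roc
#' @return distance in `[0, sqrt(2)]`.
#' @export
ed_on_roc <- function(t, model) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  sqrt(t^2 + (1 - roc(t, model))^2)
}

# Default threshold grid: spans > 6 effective SDs beyond both population
# means, so tail probabilities at the ends are < 1e-9 and curves reach their
# corners.
.threshold_grid <- function(model, n = 512) {
  s <- max(.sigma_d_eff(model), .sigma_nd_eff(model))
  lo <- min(model$pop$mu_d, model$pop$mu_nd) - 6 * s
  hi <- max(model$pop$mu_d, model$pop$mu_nd) + 6 * s
  seq(lo, hi, length.out = n)
}

#' ROC and predictive ROC curve points
#'
#' `roc_points` samples the ROC curve `(1 - Sp(d), Se(d))` and `proc_points`
#' the predictive ROC (PROC) curve `(1 - NPV(d), PPV(d))` over a threshold
#' grid spanning both population supports. The PROC curve composes the
#' positive predictive value with the inverse of the negative predictive
#' value; no elementary closed form exists, so the curve is realized by
#' threshold parametrization, which is mathematically identical on the
#' monotone range and avoids nested root-finding (see [npv_inverse()] for
#' the literal inverse).
#'
#' @param model a [test_model()]; for `proc_points` the prevalence must lie
#'   strictly inside `(0, 1)`, otherwise the predictive values degenerate.
#' @param n number of grid points, `>= 2`.
#' @return a `data.frame` with columns `d` (generating threshold), `t`
#'   (abscissa) and `y` (ordinate), ordered by increasing `t`.
#' @examples
#' tm <- test_model(population_pair(2.99, 0.75, 0, 1, 0.067), 0.023)
#' head(proc_points(tm, n = 64))
#' @export
roc_points <- function(model, n = 512) {
  stopifnot(inherits(model, "test_model"), n >= 2)
  d <- .threshold_grid(model, n)
  out <- data.frame(d = d, t = 1 - specificity(d, model),
                    y = sensitivity(d, model))
  out[order(out$t), , drop = FALSE]
}

#' @rdname roc_points
#' @export
proc_points <- function(model, n = 512) {
  stopifnot(inherits(model, "test_model"), n >= 2)
  v <- model$pop$v
  if (v <= 0 || v >= 1)
    stop("PROC curve requires prevalence strictly inside (0, 1), got v = ", v)
  d <- .threshold_grid(model, n)
  pv <- predictive_values(sensitivity(d, model), specificity(d, model), v)
  out <- data.frame(d = d, t = 1 - pv$npv, y = pv$ppv)
  out[order(out$t), , drop = FALSE]
}

#' Invert the negative predictive value in the threshold
#'
#' Finds the threshold `d` at which `NPV(d) = q` by bracketed root-finding on
#' the default threshold grid interval. NPV is increasing in `d` for usual
#' parameter settings; should the root not be bracketed (extreme parameter
#' combinations can make NPV non-monotone), an error is raised rather than a
#' branch silently chosen. Intended for validating the composed
#' predictive-ROC definition against the threshold-parametrized curve.
#'
#' @param q target NPV value.
#' @param model a [test_model()] with prevalence in `(0, 1)`.
#' @param tol absolute tolerance on `d`.
#' @return the threshold `d` with `NPV(d) = q`.
#' @export
npv_inverse <- function(q, model, tol = 1e-10) {
  stopifnot(inherits(model, "test_model"))
  v <- model$pop$v
  if (v <= 0 || v >= 1) stop("npv_inverse requires 0 < v < 1")
  g <- .threshold_grid(model, 2)
  f <- function(d)
    predictive_values(sensitivity(d, model), specificity(d, model), v)$npv - q
  stats::uniroot(f, lower = g[1], upper = g[2], tol = tol)$root
}

#' Write curve points to CSV
#'
#' Full-precision export of a `roc_points`/`proc_points` data frame with
#' columns `d`, `t`, `y`.
#'
#' @param points data frame as returned by [roc_points()] or [proc_points()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(points, path) {
  stopifnot(all(c("d", "t", "y") %in% names(points)))
  utils::write.csv(points[, c("d", "t", "y")], path, row.names = FALSE)
  invisible(path)
}
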