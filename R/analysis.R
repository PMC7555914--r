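#' Two tests on the same populations differing only in uncertainty
#'
#' Bundles two [test_model()]s that share the same [population_pair()] and
#' differ only in their standard measurement uncertainty. By convention the
#' first test is the one being compared from (it goes in the numerator of
#' ratios and relative differences).
#'
#' @param pop a [population_pair()].
#' @param u_a,u_b standard measurement uncertainties of the two tests.
#' @return an object of class `test_pair` with components `test1`, `test2`.
#' @examples
#' pair <- test_pair(population_pair(2.99, 0.75, 0, 1, 0.067), 0.023, 0.23)
#' @export
test_pair <- function(pop, u_a, u_b) {
  structure(list(test1 = test_model(pop, u_a), test2 = test_model(pop, u_b)),
            class = "test_pair")
}

#' @export
print.test_pair <- function(x, ...) {
  print(x$test1$pop)
  cat(sprintf("Test 1: u = %.4g; test 2: u = %.4g\n", x$test1$u, x$test2$u))
  invisible(x)
}

# scalar evaluation of one named measure at threshold d
.measure_value <- function(measure, d, model, loss = NULL) {
  measure <- match.arg(measure, dam_measures())
  if (measure == "r" && is.null(loss))
    stop("measure 'r' requires a loss_spec")
  dam_table(d, model, loss)[[measure]]
}

# d(Se)/du and d(Sp)/du at fixed threshold, by the chain rule through the
# effective SD: d sigma_eff / du = u / sigma_eff.
.dse_du <- function(d, model) {
  s <- .sigma_d_eff(model)
  z <- (d - model$pop$mu_d) / s
  stats::dnorm(z) * (d - model$pop$mu_d) * model$u / s^3
}

.dsp_du <- function(d, model) {
  s <- .sigma_nd_eff(model)
  z <- (d - model$pop$mu_nd) / s
  -stats::dnorm(z) * (d - model$pop$mu_nd) * model$u / s^3
}

# partial derivatives of each measure with respect to (Se, Sp); v and loss
# enter as constants
.measure_partials <- function(measure, se, sp, v, loss) {
  switch(measure,
    se  = c(1, 0),
    sp  = c(0, 1),
    ppv = {
      a <- se * v; b <- (1 - sp) * (1 - v); den <- (a + b)^2
      c(v * b / den, a * (1 - v) / den)
    },
    npv = {
      cc <- sp * (1 - v); dd <- (1 - se) * v; den <- (cc + dd)^2
      c(cc * v / den, (1 - v) * dd / den)
    },
    oda = c(v, 1 - v),
    dor = c(sp / ((1 - se)^2 * (1 - sp)), se / ((1 - se) * (1 - sp)^2)),
    lr_pos = c(1 / (1 - sp), se / (1 - sp)^2),
    lr_neg = c(-1 / sp, -(1 - se) / sp^2),
    j   = c(1, 1),
    ed  = {
      e <- sqrt((1 - se)^2 + (1 - sp)^2)
      c(-(1 - se) / e, -(1 - sp) / e)
    },
    cz  = c(sp, se),
    r   = c((loss$l_tp - loss$l_fn) * v,
            (loss$l_tn - loss$l_fp) * (1 - v))
  )
}

#' Partial derivative of a measure with respect to measurement uncertainty
#'
#' Computes the sensitivity of any of the twelve diagnostic accuracy
#' measures to the standard measurement uncertainty `u`, at a fixed
#' diagnostic threshold. The default analytic path differentiates Se and Sp
#' through the effective SD and propagates by the chain rule through the
#' measure's closed form in `(Se, Sp)`. The finite-difference path uses a
#' central difference with one level of Richardson extrapolation and step
#' `h = max(1e-6, 1e-3 u)` (the measures are even in `u`, so the stencil may
#' cross zero). At boundaries where a ratio measure is infinite the
#' derivative is undefined and `NaN` is returned with a warning.
#'
#' @param measure one of [dam_measures()].
#' @param d diagnostic threshold (scalar).
#' @param model a [test_model()].
#' @param loss a [loss_spec()], required for `measure = "r"`.
#' @param method `"analytic"` (default) or `"fd"`.
#' @param h finite-difference step; default as above.
#' @return the derivative value (scalar).
#' @examples
#' cfg <- case_study_fixture()
#' tm  <- test_model(cfg$pop, cfg$u_a)
#' d_measure_du("oda", cfg$d, tm, cfg$loss)
#' @export
d_measure_du <- function(measure, d, model, loss = NULL,
                         method = c("analytic", "fd"), h = NULL) {
  measure <- match.arg(measure, dam_measures())
  method <- match.arg(method)
  stopifnot(inherits(model, "test_model"), is.numeric(d), length(d) == 1)
  if (measure == "r" && is.null(loss))
    stop("measure 'r' requires a loss_spec")
  if (method == "fd") {
    if (is.null(h)) h <- max(1e-6, 1e-3 * model$u)
    f <- function(u) {
      m <- model
      m$u <- abs(u)  # measures depend on u only through u^2
      .measure_value(measure, d, m, loss)
    }
    u0 <- model$u
    D1 <- (f(u0 + h) - f(u0 - h)) / (2 * h)
    D2 <- (f(u0 + h / 2) - f(u0 - h / 2)) / h
    return((4 * D2 - D1) / 3)
  }
  se <- sensitivity(d, model)
  sp <- specificity(d, model)
  if (measure %in% c("dor", "lr_pos", "lr_neg") && (se %in% c(0, 1) || sp %in% c(0, 1))) {
    warning("derivative of ", measure, " undefined at a Se/Sp boundary; returning NaN",
            call. = FALSE)
    return(NaN)
  }
  p <- .measure_partials(measure, se, sp, model$pop$v, loss)
  p[1] * .dse_du(d, model) + p[2] * .dsp_du(d, model)
}

#' Compare a measure between the two tests of a pair
#'
#' Evaluates the measure for both tests at the threshold(s) `d` and returns
#' the three comparison statistics: the difference `m1 - m2`, the relative
#' difference `(m1 - m2) / m1` and the ratio `m1 / m2`, with the lower-`u`
#' test (test 1) in the numerator. A zero `m1` leaves the relative
#' difference and ratio undefined (`NaN` with a warning).
#'
#' @param measure one of [dam_measures()].
#' @param pair a [test_pair()].
#' @param d threshold(s) at which to compare.
#' @param loss a [loss_spec()], required for `measure = "r"`.
#' @return a `data.frame` with columns `d`, `m1`, `m2`, `difference`,
#'   `relative_difference`, `ratio`.
#' @examples
#' cfg <- case_study_fixture()
#' compare("j", test_pair(cfg$pop, cfg$u_a, cfg$u_b), cfg$d)
#' @export
compare <- function(measure, pair, d, loss = NULL) {
  stopifnot(inherits(pair, "test_pair"))
  m1 <- .measure_value(measure, d, pair$test1, loss)
  m2 <- .measure_value(measure, d, pair$test2, loss)
  out <- data.frame(d = d, m1 = m1, m2 = m2,
                    difference = m1 - m2,
                    relative_difference = (m1 - m2) / m1,
                    ratio = m1 / m2)
  if (any(is.nan(out$relative_difference) | is.nan(out$ratio)))
    .warn_undefined("comparison with m1 = 0")
  out
}

.objectives <- c(J = "j", ED = "ed", CZ = "cz", R = "r")
.obj_sense <- c(J = "maximize", ED = "minimize", CZ = "maximize", R = "minimize")

#' Optimal diagnostic threshold for an objective or loss function
#'
#' Finds the threshold maximizing Youden's index (`"J"`) or the concordance
#' probability (`"CZ"`), or minimizing the Euclidean distance (`"ED"`) or the
#' expected-loss risk (`"R"`). The search is deterministic: a 1000-point
#' coarse grid over the interval spanning 6 effective SDs beyond both
#' population means locates the basin, then Brent's bracketed scalar search
#' refines it to an absolute tolerance of 1e-6 in `d`. The objectives are
#' smooth, so grid-plus-refine is reliable without derivatives, and the grid
#' guards against local optima of the risk under extreme loss ratios.
#'
#' If the objective is flat over the whole interval (e.g. Youden's index
#' when the two populations coincide), the midpoint of the flat region is
#' reported with `non_unique = TRUE` instead of failing.
#'
#' @param objective one of `"J"`, `"ED"`, `"CZ"`, `"R"`.
#' @param model a [test_model()].
#' @param loss a [loss_spec()]; required for `objective = "R"`.
#' @param tol absolute tolerance on the optimal threshold.
#' @return an object of class `opt_result`: a list with `objective`,
#'   `d_opt`, `value`, `sense`, `non_unique` and `table` (the [dam_table()]
#'   evaluated at the optimum).
#' @examples
#' cfg <- case_study_fixture()
#' optimize_threshold("J", test_model(cfg$pop, cfg$u_a))  # d_opt ~ 1.637
#' @export
optimize_threshold <- function(objective = c("J", "ED", "CZ", "R"),
                               model, loss = NULL, tol = 1e-6) {
  objective <- match.arg(objective)
  stopifnot(inherits(model, "test_model"))
  if (objective == "R" && is.null(loss))
    stop("objective 'R' requires a loss_spec")
  measure <- .objectives[[objective]]
  sense <- .obj_sense[[objective]]
  sign_ <- if (sense == "maximize") 1 else -1
  f <- function(d) sign_ * .measure_value(measure, d, model, loss)

  grid <- .threshold_grid(model, 1000)
  fg <- f(grid)
  if (diff(range(fg)) < 1e-12) {
    d_opt <- mean(range(grid))
    return(structure(list(objective = objective, d_opt = d_opt,
                          value = .measure_value(measure, d_opt, model, loss),
                          sense = sense, non_unique = TRUE,
                          table = dam_table(d_opt, model, loss)),
                     class = "opt_result"))
  }
  i <- which.max(fg)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                         tol = tol / 10)
  d_opt <- opt$maximum
  structure(list(objective = objective, d_opt = d_opt,
                 value = .measure_value(measure, d_opt, model, loss),
                 sense = sense, non_unique = FALSE,
                 table = dam_table(d_opt, model, loss)),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, digits = 3, ...) {
  cat(sprintf("Objective %s (%s): optimal threshold d = %.*f (value %.*f)%s\n",
              x$objective, x$sense, digits, x$d_opt, digits, x$value,
              if (x$non_unique) " [non-unique: flat objective]" else ""))
  print(x$table, digits = digits)
  invisible(x)
}

#' Optimal thresholds of both tests for each objective
#'
#' Runs [optimize_threshold()] for both tests of a pair and every requested
#' objective, and appends the relative difference of the two optimal
#' thresholds under the `(d1 - d2) / d1` convention of [compare()].
#'
#' @param pair a [test_pair()].
#' @param loss a [loss_spec()]; required when `"R"` is among the objectives.
#' @param objectives character vector among `"J"`, `"ED"`, `"CZ"`, `"R"`.
#' @return a `data.frame` with columns `objective`, `sense`, `d_opt1`,
#'   `d_opt2`, `relative_difference`.
#' @examples
#' cfg <- case_study_fixture()
#' optimal_thresholds(test_pair(cfg$pop, cfg$u_a, cfg$u_b), cfg$loss)
#' @export
optimal_thresholds <- function(pair, loss = NULL,
                               objectives = c("J", "ED", "CZ", "R")) {
  stopifnot(inherits(pair, "test_pair"))
  rows <- lapply(objectives, function(obj) {
    o1 <- optimize_threshold(obj, pair$test1, loss)
    o2 <- optimize_threshold(obj, pair$test2, loss)
    data.frame(objective = obj, sense = o1$sense,
               d_opt1 = o1$d_opt, d_opt2 = o2$d_opt,
               relative_difference = (o1$d_opt - o2$d_opt) / o1$d_opt)
  })
  do.call(rbind, rows)
}
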