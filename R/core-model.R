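#' Binormal measurand populations
#'
#' Constructs the pair of normally distributed measurand populations that a
#' screening or diagnostic test discriminates: a diseased population with
#' mean `mu_d` and standard deviation `sigma_d`, a non-diseased population
#' with mean `mu_nd` and standard deviation `sigma_nd`, and the disease
#' prevalence `v`. All quantities are in measurand units (the package is
#' unit-agnostic; any normalization, e.g. to the non-diseased SD of a
#' log-transformed analyte, is the caller's choice).
#'
#' @param mu_d,sigma_d mean and SD of the measurand in the diseased
#'   population; `sigma_d > 0`.
#' @param mu_nd,sigma_nd mean and SD in the non-diseased population;
#'   `sigma_nd > 0`.
#' @param v disease prevalence, a probability in `[0, 1]`.
#' @return an object of class `population_pair`.
#' @examples
#' pop <- population_pair(mu_d = 2.99, sigma_d = 0.75,
#'                        mu_nd = 0, sigma_nd = 1, v = 0.067)
#' @seealso [test_model()]
#' @export
population_pair <- function(mu_d, sigma_d, mu_nd, sigma_nd, v) {
  stopifnot(is.numeric(mu_d), is.numeric(sigma_d),
            is.numeric(mu_nd), is.numeric(sigma_nd), is.numeric(v))
  if (!is.finite(sigma_d) || sigma_d <= 0)
    stop("sigma_d must be a positive finite number, got ", sigma_d)
  if (!is.finite(sigma_nd) || sigma_nd <= 0)
    stop("sigma_nd must be a positive finite number, got ", sigma_nd)
  if (!is.finite(v) || v < 0 || v > 1)
    stop("v (prevalence) must lie in [0, 1], got ", v)
  if (!is.finite(mu_d) || !is.finite(mu_nd))
    stop("population means must be finite")
  structure(list(mu_d = as.numeric(mu_d), sigma_d = as.numeric(sigma_d),
                 mu_nd = as.numeric(mu_nd), sigma_nd = as.numeric(sigma_nd),
                 v = as.numeric(v)),
            class = "population_pair")
}

#' A test measuring the binormal measurand with a given uncertainty
#'
#' Combines a [population_pair()] with one test's standard measurement
#' uncertainty `u`. The observed measurements of the test in each population
#' are normal with the population mean and the effective SD
#' `sqrt(sigma_p^2 + u^2)` (see [effective_sigma()]); a measurement above the
#' diagnostic threshold classifies the subject as test-positive.
#'
#' @param pop a [population_pair()].
#' @param u standard measurement uncertainty, same units as the SDs, `u >= 0`.
#' @return an object of class `test_model`.
#' @examples
#' pop <- population_pair(2.99, 0.75, 0, 1, 0.067)
#' tm  <- test_model(pop, u = 0.023)
#' sensitivity(2.26, tm)
#' specificity(2.26, tm)
#' @export
test_model <- function(pop, u) {
  if (!inherits(pop, "population_pair"))
    stop("pop must be a population_pair")
  if (!is.numeric(u) || !is.finite(u) || u < 0)
    stop("u (standard measurement uncertainty) must be finite and >= 0, got ", u)
  structure(list(pop = pop, u = as.numeric(u)), class = "test_model")
}

#' @export
print.population_pair <- function(x, ...) {
  cat(sprintf(
    "Binormal populations: diseased N(%.4g, %.4g), non-diseased N(%.4g, %.4g), prevalence %.4g\n",
    x$mu_d, x$sigma_d, x$mu_nd, x$sigma_nd, x$v))
  invisible(x)
}

#' @export
print.test_model <- function(x, ...) {
  print(x$pop)
  cat(sprintf("Standard measurement uncertainty u = %.4g\n", x$u))
  invisible(x)
}

#' Effective standard deviation of observed measurements
#'
#' Root-sum-of-squares combination of the biological spread of the measurand
#' in a population with the standard measurement uncertainty of the test:
#' `sqrt(sigma_p^2 + u^2)`. This is the SD of the observed (measured) values
#' in that population.
#'
#' @param sigma_p SD of the measurand in the population, `> 0`.
#' @param u standard measurement uncertainty, `>= 0`.
#' @return the effective SD, always `>= sigma_p` and increasing in `u`.
#' @examples
#' effective_sigma(3, 4)      # 5
#' effective_sigma(0.75, 0.23)
#' @export
effective_sigma <- function(sigma_p, u) {
  if (any(!is.finite(sigma_p)) || any(sigma_p <= 0))
    stop("sigma_p must be positive and finite")
  if (any(!is.finite(u)) || any(u < 0))
    stop("u must be finite and >= 0")
  sqrt(sigma_p^2 + u^2)
}

# effective SDs of a test_model in the diseased / non-diseased population
.sigma_d_eff  <- function(model) sqrt(model$pop$sigma_d^2 + model$u^2)
.sigma_nd_eff <- function(model) sqrt(model$pop$sigma_nd^2 + model$u^2)

#' Sensitivity and specificity against the diagnostic threshold
#'
#' Under the binormal model with classification rule "measurement above the
#' threshold `d` is test-positive", sensitivity is the upper-tail probability
#' of the diseased measurement distribution at `d` and specificity the
#' lower-tail probability of the non-diseased one:
#' \deqn{Se(d) = 1 - \Psi(d;\ \mu_D, \sqrt{\sigma_D^2+u^2}), \qquad
#'       Sp(d) = \Psi(d;\ \mu_{\bar D}, \sqrt{\sigma_{\bar D}^2+u^2})}
#' where \eqn{\Psi} is the normal cumulative distribution function.
#' `sensitivity` is strictly decreasing and `specificity` strictly increasing
#' in `d`; infinite thresholds return the limit values 0/1 so that plotting
#' and optimization may bracket at extremes.
#'
#' @param d diagnostic threshold(s), measurand units; may be `+-Inf`.
#' @param model a [test_model()].
#' @return probability vector of the same length as `d`.
#' @examples
#' tm <- test_model(population_pair(2.99, 0.75, 0, 1, 0.067), u = 0.023)
#' sensitivity(2.26, tm)   # ~0.8346
#' specificity(2.26, tm)   # ~0.9881
#' @export
sensitivity <- function(d, model) {
  stopifnot(inherits(model, "test_model"), is.numeric(d))
  .norm_sf(d, model$pop$mu_d, .sigma_d_eff(model))
}

#' @rdname sensitivity
#' @export
specificity <- function(d, model) {
  stopifnot(inherits(model, "test_model"), is.numeric(d))
  .norm_cdf(d, model$pop$mu_nd, .sigma_nd_eff(model))
}

#' Sensitivity as a function of specificity, and vice versa
#'
#' The two tail probabilities are linked through the threshold: given a
#' specificity `z` there is a unique threshold `d* = Psi^-1(z)` of the
#' non-diseased observed distribution, and `se_given_sp(z)` is the
#' sensitivity there. `sp_given_se` is the companion inverse. Endpoint
#' values 0 and 1 are accepted and return the corresponding limits; values
#' outside `[0, 1]` are a domain error.
#'
#' @param z specificity in `[0, 1]`.
#' @param y sensitivity in `[0, 1]`.
#' @param model a [test_model()].
#' @return probability vector.
#' @examples
#' tm <- test_model(population_pair(2.99, 0.75, 0, 1, 0.067), u = 0.023)
#' se_given_sp(specificity(2.26, tm), tm)  # equals sensitivity(2.26, tm)
#' sp_given_se(sensitivity(2.26, tm), tm)  # equals specificity(2.26, tm)
#' @export
se_given_sp <- function(z, model) {
  stopifnot(inherits(model, "test_model"), is.numeric(z))
  if (any(!is.na(z) & (z < 0 | z > 1)))
    stop("specificity z must lie in [0, 1]")
  d_star <- .norm_quantile(z, model$pop$mu_nd, .sigma_nd_eff(model))
  sensitivity(d_star, model)
}

#' @rdname se_given_sp
#' @export
sp_given_se <- function(y, model) {
  stopifnot(inherits(model, "test_model"), is.numeric(y))
  if (any(!is.na(y) & (y < 0 | y > 1)))
    stop("sensitivity y must lie in [0, 1]")
  # Se(d) = 1 - Psi(d; mu_d, sd_d): d* is the upper-tail quantile of the
  # diseased observed distribution at y (formed directly from y, not 1 - y,
  # to keep precision when y is close to 1)
  d_star <- .norm_quantile_upper(y, model$pop$mu_d, .sigma_d_eff(model))
  specificity(d_star, model)
}
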