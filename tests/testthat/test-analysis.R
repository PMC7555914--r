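test_that("analytic uncertainty derivatives match finite differences", {
  loss <- cs_loss()
  for (u in c(0.023, 0.23)) {
    m <- cs_model(u)
    for (d in c(1.5, 2.26, 2.8)) {
      for (meas in dam_measures()) {
        a <- d_measure_du(meas, d, m, loss)
        fd <- d_measure_du(meas, d, m, loss, method = "fd")
        expect_equal(a, fd, tolerance = 1e-6,
                     info = sprintf("%s at d=%g, u=%g", meas, d, u))
      }
    }
  }
})

test_that("derivative special cases vanish where symmetry demands", {
  m <- cs_model(0.1)
  # Se = 0.5 at d = mu_d for every u, so dSe/du = 0 there
  expect_equal(d_measure_du("se", m$pop$mu_d, m), 0, tolerance = 1e-14)
  expect_equal(d_measure_du("sp", m$pop$mu_nd, m), 0, tolerance = 1e-14)
  # identical populations: J is identically zero along u
  cm <- chance_model()
  for (d in c(-0.5, 1, 2.5)) {
    expect_equal(d_measure_du("j", d, cm), 0, tolerance = 1e-12)
  }
  # at u = 0 every measure is stationary in u (effective SD is even in u)
  m0 <- cs_model(0)
  expect_equal(d_measure_du("oda", 2.26, m0, cs_loss()), 0, tolerance = 1e-14)
})

test_that("two-test comparison follows the (m1-m2)/m1 convention", {
  pair <- test_pair(cs_pop(), 0.023, 0.23)
  cmp <- compare("j", pair, 2.26)
  expect_equal(cmp$difference, cmp$m1 - cmp$m2)
  expect_equal(cmp$relative_difference, (cmp$m1 - cmp$m2) / cmp$m1)
  expect_equal(cmp$ratio, cmp$m1 / cmp$m2)
  # equal uncertainties: all comparisons collapse
  same <- test_pair(cs_pop(), 0.1, 0.1)
  for (meas in c("se", "ppv", "dor", "r")) {
    cmp <- compare(meas, same, 2.26, cs_loss())
    expect_equal(cmp$difference, 0)
    expect_equal(cmp$relative_difference, 0)
    expect_equal(cmp$ratio, 1)
  }
  expect_no_warning(compare("j", pair, 1.5)) # finite nonzero m1
})

test_that("optimizer finds the equal-variance symmetric optimum", {
  m <- test_model(population_pair(3, 1, 1, 1, 0.2), 0.4)
  res <- optimize_threshold("J", m)
  expect_equal(res$d_opt, 2, tolerance = 1e-6)
  expect_false(res$non_unique)
  expect_equal(res$sense, "maximize")
  # local optimality
  expect_gt(res$value, res$table$j[1] - 1e-12)
  jval <- function(d) sensitivity(d, m) + specificity(d, m) - 1
  for (delta in c(1e-4, 1e-3)) {
    expect_lt(jval(res$d_opt + delta), res$value + 1e-12)
    expect_lt(jval(res$d_opt - delta), res$value + 1e-12)
  }
})

test_that("J optimum is the density crossing, matching a brute-force scan", {
  for (u in c(0.023, 0.23)) {
    m <- cs_model(u)
    res <- optimize_threshold("J", m)
    # oracle 1: exhaustive grid scan
    d <- seq(-3, 7, length.out = 1e5)
    j <- sensitivity(d, m) + specificity(d, m) - 1
    expect_equal(res$d_opt, d[which.max(j)], tolerance = 1e-4)
    # oracle 2: root of f_D(d) = f_ND(d) between the means
    f <- function(d)
      dnorm(d, m$pop$mu_d, sqrt(m$pop$sigma_d^2 + m$u^2)) -
      dnorm(d, m$pop$mu_nd, sqrt(m$pop$sigma_nd^2 + m$u^2))
    root <- uniroot(f, c(m$pop$mu_nd, m$pop$mu_d), tol = 1e-12)$root
    expect_equal(res$d_opt, root, tolerance = 1e-6)
  }
})

test_that("objective optima are invariant to prevalence and losses except risk", {
  for (obj in c("J", "ED", "CZ")) {
    d_ref <- optimize_threshold(obj, cs_model(0.023))$d_opt
    for (v in c(0.01, 0.3, 0.9)) {
      expect_equal(optimize_threshold(obj, cs_model(0.023, v = v))$d_opt,
                   d_ref, tolerance = 1e-6)
    }
    expect_equal(
      optimize_threshold(obj, cs_model(0.023), loss_spec(5, 1, 7, 2, 3))$d_opt,
      d_ref, tolerance = 1e-6)
  }
})

test_that("risk optimum drops as false negatives grow costlier", {
  m <- cs_model(0.023)
  lfn <- c(10, 30, 100, 300, 1000)
  d_opt <- vapply(lfn, function(l)
    optimize_threshold("R", m, loss_spec(1, 0, l, 0, 76))$d_opt, numeric(1))
  expect_true(all(diff(d_opt) < 0))
})

test_that("a flat objective reports a non-unique optimum instead of failing", {
  res <- optimize_threshold("J", chance_model())
  expect_true(res$non_unique)
  expect_equal(res$value, 0, tolerance = 1e-12)
})

test_that("optimal_thresholds tabulates both tests with relative differences", {
  tab <- optimal_thresholds(test_pair(cs_pop(), 0.023, 0.23), cs_loss())
  expect_equal(tab$objective, c("J", "ED", "CZ", "R"))
  expect_equal(tab$relative_difference,
               (tab$d_opt1 - tab$d_opt2) / tab$d_opt1)
  expect_error(optimal_thresholds(test_pair(cs_pop(), 0.023, 0.23)),
               "loss")
})
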