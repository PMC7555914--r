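test_that("predictive values follow Bayes' rule and depend on prevalence", {
  pv <- predictive_values(0.8, 0.8, 0.5)
  expect_equal(pv$ppv, 0.8)
  expect_equal(pv$npv, 0.8)
  expect_equal(predictive_values(1, 1, 0.3), list(ppv = 1, npv = 1))
  # direct arithmetic at the case-study operating point
  pv <- predictive_values(0.8346925260759335, 0.9880708194550613, 0.067)
  expect_equal(pv$ppv, 0.8340162920293757, tolerance = 1e-12)
  expect_equal(pv$npv, 0.9881283540445185, tolerance = 1e-12)
  # PPV increases and NPV decreases with prevalence
  v <- seq(0.01, 0.99, by = 0.01)
  pv <- predictive_values(0.8, 0.9, v)
  expect_true(all(diff(pv$ppv) > 0))
  expect_true(all(diff(pv$npv) < 0))
  # 0/0 is NaN with a warning, not an error
  expect_warning(pv <- predictive_values(0.5, 1, 0), "undefined")
  expect_true(is.nan(pv$ppv))
})

test_that("likelihood ratios and DOR obey their boundary conventions", {
  rm <- ratio_measures(0.8, 0.9)
  expect_equal(rm$lr_pos, 8)
  expect_equal(rm$lr_neg, 2 / 9)
  expect_equal(rm$dor, 36)
  rm <- ratio_measures(0.5, 0.5)
  expect_equal(rm, list(dor = 1, lr_pos = 1, lr_neg = 1))
  # Sp = 1: LR+ and DOR infinite; Se = 1: LR- = 0, DOR infinite
  rm <- ratio_measures(0.8, 1)
  expect_identical(rm$lr_pos, Inf)
  expect_identical(rm$dor, Inf)
  rm <- ratio_measures(1, 0.9)
  expect_identical(rm$lr_neg, 0)
  expect_identical(rm$dor, Inf)
  expect_warning(rm <- ratio_measures(0, 1), "undefined")
  expect_true(is.nan(rm$lr_pos))
})

test_that("objective measures are exact algebraic forms of (Se, Sp)", {
  expect_equal(objective_measures(1, 1), list(j = 1, ed = 0, cz = 1))
  om <- objective_measures(0.5, 0.5)
  expect_equal(om$j, 0)
  expect_equal(om$ed, sqrt(0.5))
  expect_equal(om$cz, 0.25)
  om <- objective_measures(0.8, 0.9)
  expect_equal(om$j, 0.7)
  expect_equal(om$ed, sqrt(0.05))
  expect_equal(om$cz, 0.72)
})

test_that("risk is the expected loss over the four outcomes", {
  l <- loss_spec(1, 0, 0, 0, 0)
  expect_equal(risk(0.3, 0.7, 0.2, l), 1)
  # perfect test: only TN and TP terms survive
  l <- loss_spec(2, 3, 5, 7, 11)
  expect_equal(risk(1, 1, 0.25, l), 2 + 3 * 0.75 + 7 * 0.25)
  # case-study operating point, frozen from direct arithmetic
  expect_equal(risk(0.8346925260759335, 0.9880708194550613, 0.067, cs_loss()),
               2.953434409371762, tolerance = 1e-12)
  # misclassification-probability identity: v(1-Se)+(1-v)(1-Sp) = 1 - ODA
  l <- loss_spec(0, 0, 1, 0, 1)
  for (se in c(0.2, 0.8)) for (sp in c(0.6, 0.95)) for (v in c(0.05, 0.5)) {
    expect_equal(risk(se, sp, v, l), 1 - oda(se, sp, v), tolerance = 1e-14)
  }
  expect_error(loss_spec(1, 0, Inf, 0, 0), "finite")
})

test_that("oda is the prevalence-weighted accuracy", {
  expect_equal(oda(1, 1, 0.3), 1)
  expect_equal(oda(0.8, 0.9, 0), 0.9)
  expect_equal(oda(0.8346925260759335, 0.9880708194550613, 0.067),
               0.9777944737986598, tolerance = 1e-12)
})

test_that("dam_table assembles consistent rows over thresholds", {
  m <- cs_model(0.023)
  tab <- dam_table(c(1, 2.26, 4), m, cs_loss())
  expect_s3_class(tab, "dam_table")
  expect_equal(nrow(tab), 3)
  # internal identities hold exactly
  expect_equal(tab$j, tab$se + tab$sp - 1)
  expect_equal(tab$cz, tab$se * tab$sp)
  expect_equal(tab$ed, sqrt((1 - tab$se)^2 + (1 - tab$sp)^2))
  expect_equal(tab$dor, tab$lr_pos / tab$lr_neg, tolerance = 1e-12)
  # chance-line row
  cm <- chance_model()
  row <- dam_table(0.7, cm, cs_loss())
  expect_equal(row$j, 0, tolerance = 1e-14)
  expect_equal(row$dor, 1, tolerance = 1e-12)
  # boundary threshold: no positives at all (PPV/LR+ legitimately 0/0 there)
  row <- suppressWarnings(dam_table(Inf, m, cs_loss()))
  expect_equal(row$se, 0)
  expect_equal(row$sp, 1)
  expect_equal(row$npv, 1 - m$pop$v)
})

test_that("prevalence moves only the prevalence-dependent measures", {
  invariant <- c("se", "sp", "dor", "lr_pos", "lr_neg", "j", "ed", "cz")
  dependent <- c("ppv", "npv", "oda", "r")
  rows <- lapply(c(0.05, 0.2, 0.5, 0.9), function(v)
    dam_table(2.26, cs_model(0.023, v = v), cs_loss()))
  for (meas in invariant) {
    vals <- vapply(rows, function(r) r[[meas]], numeric(1))
    expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12,
                 info = meas)
  }
  for (meas in dependent) {
    vals <- vapply(rows, function(r) r[[meas]], numeric(1))
    expect_gt(max(vals) - min(vals), 1e-4)
  }
})
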