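#' Expected-loss constants for the four test outcomes
#'
#' The risk of applying a test at a threshold is the expected loss over the
#' four classification outcomes plus a fixed loss `l0` of the testing
#' procedure itself. The five constants live on one common scale; no sign
#' constraint is imposed, and "lower risk is better" is fixed by the use of
#' minimization in [optimize_threshold()].
#'
#' @param l0 loss of the testing procedure itself.
#' @param l_tn,l_fn,l_tp,l_fp expected losses of a true-negative,
#'   false-negative, true-positive and false-positive outcome.
#' @return an object of class `loss_spec`.
#' @examples
#' loss_spec(l0 = 1, l_tn = 0, l_fn = 100, l_tp = 0, l_fp = 76)
#' @export
loss_spec <- function(l0, l_tn, l_fn, l_tp, l_fp) {
  vals <- c(l0 = l0, l_tn = l_tn, l_fn = l_fn, l_tp = l_tp, l_fp = l_fp)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("all five loss constants must be finite numbers")
  structure(as.list(as.numeric(vals)) |> stats::setNames(names(vals)),
            class = "loss_spec")
}

#' @export
print.loss_spec <- function(x, ...) {
  cat(sprintf("Losses: l0 = %g, TN = %g, FN = %g, TP = %g, FP = %g\n",
              x$l0, x$l_tn, x$l_fn, x$l_tp, x$l_fp))
  invisible(x)
}

.warn_undefined <- function(what) {
  warning(sprintf("%s undefined (0/0) for some inputs; returning NaN", what),
          call. = FALSE)
}

#' Positive and negative predictive values
#'
#' Bayes' rule applied to the test outcome:
#' `PPV = Se v / (Se v + (1 - Sp)(1 - v))` and
#' `NPV = Sp (1 - v) / (Sp (1 - v) + (1 - Se) v)`.
#' Both depend on the prevalence `v`, unlike sensitivity and specificity.
#' Indeterminate `0/0` cases (e.g. `v = 0` with `Sp = 1`) return `NaN` with a
#' warning rather than an error, so that threshold sweeps may pass through
#' boundaries.
#'
#' @param se,sp sensitivity and specificity, probabilities.
#' @param v prevalence in `[0, 1]`.
#' @return a list with components `ppv` and `npv`.
#' @examples
#' predictive_values(0.8346, 0.9881, 0.067)
#' @export
predictive_values <- function(se, sp, v) {
  stopifnot(all(se >= 0 & se <= 1), all(sp >= 0 & sp <= 1),
            all(v >= 0 & v <= 1))
  ppv <- se * v / (se * v + (1 - sp) * (1 - v))
  npv <- sp * (1 - v) / (sp * (1 - v) + (1 - se) * v)
  if (any(is.nan(ppv)) || any(is.nan(npv)))
    .warn_undefined("predictive value")
  list(ppv = ppv, npv = npv)
}

#' Likelihood ratios and the diagnostic odds ratio
#'
#' `LR+ = Se / (1 - Sp)`, `LR- = (1 - Se) / Sp` and `DOR = LR+ / LR-`.
#' These are prevalence-invariant. Boundary conventions: `Sp = 1` gives
#' `LR+ = DOR = Inf`; `Se = 1` gives `LR- = 0` and `DOR = Inf`. Indeterminate
#' combinations yield `NaN` with a warning.
#'
#' @inheritParams predictive_values
#' @return a list with components `dor`, `lr_pos`, `lr_neg`.
#' @examples
#' ratio_measures(0.8, 0.9)  # dor 36, lr_pos 8, lr_neg 2/9
#' @export
ratio_measures <- function(se, sp) {
  stopifnot(all(se >= 0 & se <= 1), all(sp >= 0 & sp <= 1))
  lr_pos <- se / (1 - sp)
  lr_neg <- (1 - se) / sp
  dor <- lr_pos / lr_neg
  # Inf/Inf or 0/0 never arise jointly except at degenerate corners; recover
  # the stated conventions there
  dor[se == 1 & sp < 1] <- Inf
  if (any(is.nan(lr_pos)) || any(is.nan(lr_neg)) || any(is.nan(dor)))
    .warn_undefined("ratio measure")
  list(dor = dor, lr_pos = lr_pos, lr_neg = lr_neg)
}

#' Objective measures of a ROC point
#'
#' Youden's index `J = Se + Sp - 1`, the Euclidean distance
#' `ED = sqrt((1 - Se)^2 + (1 - Sp)^2)` of the point `(Se, Sp)` from the
#' perfect-accuracy point `(1, 1)`, and the concordance probability
#' `CZ = Se * Sp`. All three are prevalence-invariant and are the objective
#' functions used for threshold optimization (maximize J and CZ, minimize ED).
#'
#' @inheritParams predictive_values
#' @return a list with components `j`, `ed`, `cz`.
#' @examples
#' objective_measures(0.8, 0.9)  # j 0.7, ed sqrt(0.05), cz 0.72
#' @export
objective_measures <- function(se, sp) {
  stopifnot(all(se >= 0 & se <= 1), all(sp >= 0 & sp <= 1))
  list(j = se + sp - 1,
       ed = sqrt((1 - se)^2 + (1 - sp)^2),
       cz = se * sp)
}

#' Overall diagnostic accuracy
#'
#' The prevalence-weighted probability of a correct classification:
#' `ODA = Se v + Sp (1 - v)`.
#'
#' @inheritParams predictive_values
#' @return probability vector.
#' @examples
#' oda(0.8346, 0.9881, 0.067)
#' @export
oda <- function(se, sp, v) {
  stopifnot(all(se >= 0 & se <= 1), all(sp >= 0 & sp <= 1),
            all(v >= 0 & v <= 1))
  se * v + sp * (1 - v)
}

#' Expected-loss risk of a test
#'
#' The expected loss over the four outcomes at their binormal probabilities,
#' plus the procedure loss:
#' `R = l0 + l_tn Sp (1 - v) + l_fn (1 - Se) v + l_tp Se v + l_fp (1 - Sp)(1 - v)`.
#' Linear in each loss constant.
#'
#' @inheritParams predictive_values
#' @param loss a [loss_spec()].
#' @return risk in loss units.
#' @examples
#' risk(0.8346, 0.9881, 0.067, loss_spec(1, 0, 100, 0, 76))  # ~3.95
#' @export
risk <- function(se, sp, v, loss) {
  stopifnot(inherits(loss, "loss_spec"),
            all(se >= 0 & se <= 1), all(sp >= 0 & sp <= 1),
            all(v >= 0 & v <= 1))
  loss$l0 + loss$l_tn * sp * (1 - v) + loss$l_fn * (1 - se) * v +
    loss$l_tp * se * v + loss$l_fp * (1 - sp) * (1 - v)
}

#' The names of the twelve diagnostic accuracy measures
#'
#' In the order used throughout the package: sensitivity, specificity,
#' positive and negative predictive value, overall diagnostic accuracy,
#' diagnostic odds ratio, likelihood ratios, Youden's index, Euclidean
#' distance, concordance probability and risk.
#'
#' @return character vector of measure names.
#' @export
dam_measures <- function() {
  c("se", "sp", "ppv", "npv", "oda", "dor", "lr_pos", "lr_neg",
    "j", "ed", "cz", "r")
}

#' All diagnostic accuracy measures of a test at a threshold
#'
#' Evaluates sensitivity and specificity of the test at the threshold(s) `d`
#' and from them every measure of [dam_measures()], using the prevalence
#' stored in the model's population pair. This is the calculator row: one row
#' per threshold with columns `d`, `se`, `sp`, `ppv`, `npv`, `oda`, `dor`,
#' `lr_pos`, `lr_neg`, `j`, `ed`, `cz`, `r`.
#'
#' @param d diagnostic threshold(s); may include `+-Inf`.
#' @param model a [test_model()].
#' @param loss a [loss_spec()]; if `NULL` the risk column is `NA`.
#' @return a `data.frame` of class `dam_table`.
#' @examples
#' cfg <- case_study_fixture()
#' dam_table(cfg$d, test_model(cfg$pop, cfg$u_a), cfg$loss)
#' @export
dam_table <- function(d, model, loss = NULL) {
  stopifnot(inherits(model, "test_model"))
  se <- sensitivity(d, model)
  sp <- specificity(d, model)
  v <- model$pop$v
  pv <- predictive_values(se, sp, v)
  rm <- ratio_measures(se, sp)
  om <- objective_measures(se, sp)
  r <- if (is.null(loss)) rep(NA_real_, length(d)) else risk(se, sp, v, loss)
  out <- data.frame(d = d, se = se, sp = sp, ppv = pv$ppv, npv = pv$npv,
                    oda = oda(se, sp, v), dor = rm$dor, lr_pos = rm$lr_pos,
                    lr_neg = rm$lr_neg, j = om$j, ed = om$ed, cz = om$cz,
                    r = r)
  class(out) <- c("dam_table", "data.frame")
  out
}

#' @export
print.dam_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(col) round(col, digits))
  print(y, row.names = FALSE)
  invisible(x)
}
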