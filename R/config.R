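#' Run configuration
#'
#' Aggregates everything one analysis run needs: the population pair, the
#' two tests' uncertainties, an optional fixed diagnostic threshold, the
#' loss constants and an optional sweep axis specification.
#'
#' @param pop a [population_pair()].
#' @param u_a,u_b standard measurement uncertainties of the two tests.
#' @param d optional fixed diagnostic threshold.
#' @param loss a [loss_spec()] or `NULL`.
#' @param sweep optional list with fields `axis` (one of `"threshold"`,
#'   `"prevalence"`, `"uncertainty"`, `"se"`, `"sp"`), `from`, `to`, `n`
#'   (`n >= 2`, `from < to`, both finite).
#' @return an object of class `run_config`.
#' @export
run_config <- function(pop, u_a, u_b, d = NULL, loss = NULL, sweep = NULL) {
  stopifnot(inherits(pop, "population_pair"))
  test_model(pop, u_a); test_model(pop, u_b)  # validate u's
  if (!is.null(d) && (!is.numeric(d) || !is.finite(d)))
    stop("d must be a finite number")
  if (!is.null(loss) && !inherits(loss, "loss_spec"))
    stop("loss must be a loss_spec")
  if (!is.null(sweep)) sweep <- .validate_sweep(sweep)
  structure(list(pop = pop, u_a = as.numeric(u_a), u_b = as.numeric(u_b),
                 d = if (is.null(d)) NULL else as.numeric(d),
                 loss = loss, sweep = sweep),
            class = "run_config")
}

.sweep_axes <- c("threshold", "prevalence", "uncertainty", "se", "sp")

.validate_sweep <- function(sweep) {
  for (f in c("axis", "from", "to", "n"))
    if (is.null(sweep[[f]])) stop("sweep is missing required field '", f, "'")
  if (!sweep$axis %in% .sweep_axes)
    stop("sweep axis must be one of: ", paste(.sweep_axes, collapse = ", "))
  if (!is.numeric(sweep$from) || !is.numeric(sweep$to) ||
      !is.finite(sweep$from) || !is.finite(sweep$to))
    stop("sweep 'from'/'to' must be finite numbers")
  if (sweep$from >= sweep$to)
    stop("sweep range must be ordered: from < to")
  if (!is.numeric(sweep$n) || sweep$n < 2)
    stop("sweep 'n' must be >= 2")
  sweep[c("axis", "from", "to", "n")]
}

.config_fields <- c("mu_d", "sigma_d", "mu_nd", "sigma_nd", "v", "u_a", "u_b")
.loss_fields <- c("l0", "l_tn", "l_fn", "l_tp", "l_fp")

#' Read and write run configurations
#'
#' `load_config` reads a YAML (`.yaml`/`.yml`) or JSON (`.json`)
#' configuration file, sniffed by extension, validates every field and
#' returns a [run_config()]. Field names match the glossary symbols
#' (`mu_d`, `sigma_d`, `mu_nd`, `sigma_nd`, `v`, `u_a`, `u_b`, `d`,
#' `l0`, `l_tn`, `l_fn`, `l_tp`, `l_fp`, optional `sweep`) so transcribing a
#' parameter table is mechanical. Errors name the offending field.
#' `write_config` is the exact inverse; `load_config(write_config(cfg))`
#' returns an equal configuration.
#'
#' @param path configuration file path.
#' @param config a [run_config()].
#' @return `load_config`: a [run_config()]. `write_config`: `path`,
#'   invisibly.
#' @examples
#' cfg <- case_study_fixture()
#' p <- tempfile(fileext = ".yaml")
#' write_config(cfg, p)
#' identical(load_config(p), cfg)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unrecognized config extension '.", ext, "' (expected .yaml/.yml/.json)"))
  for (f in .config_fields) {
    if (is.null(raw[[f]])) stop("config is missing required field '", f, "'")
    if (!is.numeric(raw[[f]])) stop("config field '", f, "' must be numeric")
  }
  pop <- tryCatch(
    population_pair(raw$mu_d, raw$sigma_d, raw$mu_nd, raw$sigma_nd, raw$v),
    error = function(e) stop("invalid config: ", conditionMessage(e), call. = FALSE))
  loss <- NULL
  if (any(.loss_fields %in% names(raw))) {
    missing <- setdiff(.loss_fields, names(raw))
    if (length(missing))
      stop("config has a partial loss specification; missing: ",
           paste(missing, collapse = ", "))
    if (!all(vapply(raw[.loss_fields], is.numeric, logical(1))))
      stop("loss fields must be numeric")
    loss <- loss_spec(raw$l0, raw$l_tn, raw$l_fn, raw$l_tp, raw$l_fp)
  }
  run_config(pop, raw$u_a, raw$u_b, d = raw$d, loss = loss, sweep = raw$sweep)
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(mu_d = config$pop$mu_d, sigma_d = config$pop$sigma_d,
              mu_nd = config$pop$mu_nd, sigma_nd = config$pop$sigma_nd,
              v = config$pop$v, u_a = config$u_a, u_b = config$u_b)
  if (!is.null(config$d)) out$d <- config$d
  if (!is.null(config$loss))
    out <- c(out, stats::setNames(unclass(config$loss), .loss_fields))
  if (!is.null(config$sweep)) out$sweep <- config$sweep
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' The OGTT glucose case-study parameters
#'
#' Returns the bundled normalized two-hour postprandial glucose (OGTT)
#' case-study configuration: log-transformed measurand means and SDs
#' normalized to the non-diseased SD (`mu_d = 2.99`, `sigma_d = 0.75`,
#' `mu_nd = 0`, `sigma_nd = 1`), diabetes prevalence `v = 0.067`, the
#' normalized diagnostic threshold `d = 2.26` (the 11.1 mmol/L criterion),
#' the two tests' standard measurement uncertainties `u_a = 0.023` and
#' `u_b = 0.23` (coefficients of variation of 1% and 10%), and losses
#' `l0 = 1, l_tn = 0, l_fn = 100, l_tp = 0, l_fp = 76`.
#'
#' @return a [run_config()].
#' @examples
#' cfg <- case_study_fixture()
#' cfg$pop$v   # 0.067
#' @export
case_study_fixture <- function() {
  path <- system.file("extdata", "case_study.yaml", package = "damu",
                      mustWork = TRUE)
  load_config(path)
}
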