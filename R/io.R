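# CSV round trip for patient records and YAML round trip for cohort
# configurations.

#' Write / read a cohort as CSV
#'
#' The file has a header `time,event,<covariates...>`; `event` is coded
#' 0 (censored), 1, 2.  Reading validates the file and reports offending
#' line numbers (counting the header as line 1); categorical columns are
#' restored to factors when `factor_levels` is given.
#'
#' @param records Cohort data frame (as from [simulate_cohort()]).
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a tibble.
#' @export
write_cohort <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)))
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_cohort
#' @param factor_levels Named list mapping column names to their factor
#'   levels (reference first); default restores the categorical columns of
#'   [default_cohort_config()] when present.
#' @export
read_cohort <- function(path, factor_levels = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time", "event") %in% names(raw))) {
    stop("cohort file must have `time` and `event` columns.", call. = FALSE)
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("malformed cohort file; offending line(s): ",
         paste(unique(prob$row + 1L), collapse = ", "), call. = FALSE)
  }
  bad_t <- which(!is.finite(raw$time) | raw$time <= 0)
  if (length(bad_t)) {
    stop("non-positive or missing follow-up time on line(s): ",
         paste(bad_t + 1L, collapse = ", "), call. = FALSE)
  }
  bad_e <- which(!(raw$event %in% c(0, 1, 2)))
  if (length(bad_e)) {
    stop("unknown event code on line(s): ",
         paste(bad_e + 1L, collapse = ", "), call. = FALSE)
  }
  raw$event <- as.integer(raw$event)
  if (is.null(factor_levels)) {
    cfg <- default_cohort_config()
    factor_levels <- lapply(
      Filter(function(s) s$type == "categorical", cfg$covariates),
      function(s) s$labels)
  }
  for (nm in intersect(names(factor_levels), names(raw))) {
    raw[[nm]] <- factor(raw[[nm]], levels = factor_levels[[nm]])
  }
  raw
}

#' Write / read a cohort configuration as YAML
#'
#' Serializes a [cohort_config()] (including the true cause models) so a
#' simulation recipe can be shipped alongside its outputs.
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   restored [cohort_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  ser_cm <- function(cm) list(
    theta = cm$params$theta, gamma = cm$params$gamma, rate = cm$params$rate,
    beta = as.list(cm$beta))
  obj <- list(
    n = config$n, study_years = config$study_years,
    seed = config$seed, censoring = config$censoring,
    on_invalid = config$on_invalid,
    covariates = config$covariates,
    truth = list(formula = deparse(config$truth$formula),
                 cause1 = ser_cm(config$truth$cause1),
                 cause2 = ser_cm(config$truth$cause2))
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  de_cm <- function(l) cause_model(
    gomp_params(l$theta, l$gamma, l$rate),
    stats::setNames(as.numeric(unlist(l$beta)), names(l$beta)))
  covs <- lapply(obj$covariates, function(s) {
    if (s$type == "normal") {
      cov_normal(s$mean, s$sd, s$lower %||% -Inf, s$upper %||% Inf)
    } else {
      cov_categorical(unlist(s$labels), unlist(s$probs))
    }
  })
  cohort_config(
    n = obj$n, covariates = covs,
    truth = list(formula = stats::as.formula(obj$truth$formula),
                 cause1 = de_cm(obj$truth$cause1),
                 cause2 = de_cm(obj$truth$cause2)),
    study_years = obj$study_years, seed = obj$seed,
    censoring = obj$censoring %||% "uniform",
    on_invalid = obj$on_invalid %||% "rescale")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
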