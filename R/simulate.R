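# Synthetic competing-risks cohort generator.
#
# Generation is cause-label-first: each subject's eventual cause is drawn
# from a multinomial on the sub-distribution plateaus at their covariates,
# and the event time is then drawn from that cause's conditional (proper)
# distribution by inverse transform.  This reproduces the model's
# sub-distribution functions exactly, which is the structure the fitter
# assumes; a latent-time race construction would not.

#' Covariate distribution specifications
#'
#' Building blocks for the `covariates` list of a [cohort_config()]:
#' truncated normal for labs and age, categorical (first label = reference
#' category) for graded clinical variables.
#'
#' @param mean,sd Location and scale of the untruncated normal.
#' @param lower,upper Truncation bounds (use finite bounds for covariates
#'   that carry effects, so the joint-validity check has a bounded support).
#' @param labels Category labels, reference first.
#' @param probs Category probabilities, summing to 1.
#' @return A specification list.
#' @export
cov_normal <- function(mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0, lower < upper)
  list(type = "normal", mean = mean, sd = sd, lower = lower, upper = upper)
}

#' @rdname cov_normal
#' @export
cov_categorical <- function(labels, probs) {
  stopifnot(length(labels) == length(probs), length(labels) >= 2)
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("categorical probabilities must sum to 1 (got ", sum(probs), ").",
         call. = FALSE)
  }
  if (any(probs < 0)) stop("probabilities must be non-negative.", call. = FALSE)
  list(type = "categorical", labels = as.character(labels),
       probs = as.numeric(probs))
}

.draw_one_cov <- function(spec, n) {
  switch(spec$type,
    normal = {
      plo <- stats::pnorm(spec$lower, spec$mean, spec$sd)
      phi <- stats::pnorm(spec$upper, spec$mean, spec$sd)
      stats::qnorm(stats::runif(n, plo, phi), spec$mean, spec$sd)
    },
    categorical = {
      factor(sample(spec$labels, n, replace = TRUE, prob = spec$probs),
             levels = spec$labels)
    },
    stop("unknown covariate spec type: ", spec$type, call. = FALSE)
  )
}

#' Synthetic cohort recipe
#'
#' Bundles everything needed to simulate one competing-risks cohort:
#' size, covariate distributions, the true [cause_model()]s of both causes,
#' an administrative censoring window (uniform entry over the study length,
#' no loss to follow-up), and a seed.
#'
#' @param n Cohort size (>= 1).
#' @param covariates Named list of [cov_normal()] / [cov_categorical()]
#'   specifications.
#' @param truth List with `formula` (one-sided, over covariate names),
#'   `cause1` and `cause2` ([cause_model()]s whose `beta` names match the
#'   design columns of `formula`).
#' @param study_years Length of the enrolment window (years); each subject's
#'   administrative censoring time is uniform on (0, `study_years`).
#' @param seed Default seed used by [simulate_cohort()].
#' @param censoring `"uniform"` (default): administrative censoring times
#'   uniform on (0, `study_years`), i.e. uniform enrolment over the study
#'   window; `"fixed"`: every subject censored at `study_years`.
#' @param on_invalid What to do for subjects whose two plateaus sum above 1
#'   (possible for extreme covariate draws): `"rescale"` renormalizes the
#'   two cause probabilities to sum to 1 with a warning, `"error"` aborts.
#' @return An object of class `cohort_config`.
#' @seealso [default_cohort_config()] for the packaged dialysis-cohort
#'   defaults.
#' @export
cohort_config <- function(n, covariates, truth, study_years = 4,
                          seed = NULL, censoring = c("uniform", "fixed"),
                          on_invalid = c("rescale", "error")) {
  stopifnot(n >= 1, study_years > 0)
  on_invalid <- match.arg(on_invalid)
  censoring <- match.arg(censoring)
  stopifnot(is.list(covariates), length(names(covariates)) == length(covariates))
  for (nm in names(covariates)) {
    sp <- covariates[[nm]]
    if (!is.list(sp) || is.null(sp$type)) {
      stop("covariate `", nm, "` must be a cov_normal()/cov_categorical() spec.",
           call. = FALSE)
    }
    if (sp$type == "categorical" && abs(sum(sp$probs) - 1) > 1e-12) {
      stop("probabilities of `", nm, "` must sum to 1.", call. = FALSE)
    }
  }
  stopifnot(inherits(truth$cause1, "cause_model"),
            inherits(truth$cause2, "cause_model"),
            inherits(truth$formula, "formula"))
  structure(list(n = as.integer(n), covariates = covariates, truth = truth,
                 study_years = study_years, seed = seed,
                 censoring = censoring, on_invalid = on_invalid),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n = %d, study window = %g yr, seed = %s\n",
              x$n, x$study_years,
              if (is.null(x$seed)) "unset" else format(x$seed)))
  cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  cat("  truth formula:", deparse(x$truth$formula), "\n")
  for (k in 1:2) {
    m <- x$truth[[paste0("cause", k)]]
    cat(sprintf("  cause %d plateau (baseline): %.4g\n", k,
                gomp_plateau(m$params)))
  }
  invisible(x)
}

#' Draw covariates from a cohort configuration
#'
#' Draws only the covariate block (no event times); used for
#' covariate-distribution summaries and for averaging model quantities over
#' the covariate mix.
#'
#' @param config A [cohort_config()].
#' @param n Number of subjects (defaults to `config$n`).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A tibble with one column per covariate.
#' @export
draw_covariates <- function(config, n = config$n, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed)) stop("a seed is required (argument or config$seed).",
                          call. = FALSE)
  withr::with_seed(seed, {
    tibble::as_tibble(lapply(config$covariates, .draw_one_cov, n = n))
  })
}

# design matrix of the truth formula (no intercept)
.truth_design <- function(config, covs) {
  X <- stats::model.matrix(config$truth$formula, covs)
  X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
}

# per-subject cause probabilities (plateaus), with the configured policy
# for profiles where they sum above 1
.cause_probs <- function(config, X) {
  p1 <- cause_plateau(X, config$truth$cause1)
  p2 <- cause_plateau(X, config$truth$cause2)
  bad <- p1 + p2 > 1
  if (any(bad)) {
    if (config$on_invalid == "error") {
      stop(sum(bad), " subject(s) have sub-distribution plateaus summing ",
           "above 1; the configuration is invalid over its covariate support.",
           call. = FALSE)
    }
    warning("renormalized cause probabilities for ", sum(bad),
            " subject(s) with plateau sum > 1.", call. = FALSE)
    tot <- p1[bad] + p2[bad]
    p1[bad] <- p1[bad] / tot
    p2[bad] <- p2[bad] / tot
  }
  cbind(p1, p2)
}

# conditional inverse transform: time of cause k given the cause occurs
.quantile_at <- function(u, rate, theta, gamma) {
  q <- -log1p(-u^(1 / theta))
  if (abs(gamma) < .GAMMA_EPS) q / rate else log1p(gamma * q / rate) / gamma
}

#' Simulate one competing-risks cohort
#'
#' Per subject: draw covariates; draw the eventual cause (cause 1, cause 2,
#' or neither) from the plateaus at those covariates; if a cause occurs,
#' draw its latent time from the conditional sub-distribution by inverse
#' transform; apply administrative censoring uniform on (0, study window).
#' Subjects whose latent event falls after their censoring time — or who
#' never experience either cause — are censored at the censoring time.
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed (defaults to `config$seed`); the same seed always
#'   yields an identical cohort.
#' @return A tibble with `time` (years, > 0), `event` (0 censored / 1 / 2),
#'   and the covariate columns.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed)) stop("a seed is required (argument or config$seed).",
                          call. = FALSE)
  n <- config$n
  withr::with_seed(seed, {
    covs <- tibble::as_tibble(lapply(config$covariates, .draw_one_cov, n = n))
    X <- .truth_design(config, covs)
    pr <- .cause_probs(config, X)
    u <- stats::runif(n)
    cause <- ifelse(u < pr[, 1], 1L, ifelse(u < pr[, 1] + pr[, 2], 2L, 0L))
    latent <- rep(Inf, n)
    for (k in 1:2) {
      ik <- cause == k
      if (!any(ik)) next
      cm <- config$truth[[paste0("cause", k)]]
      pa <- .params_at(X[ik, , drop = FALSE], cm)
      v <- stats::runif(sum(ik))
      # conditional draw: u2 uniform on (0, plateau)
      pk <- .plateau_at(pa$rate, pa$theta, pa$gamma)
      latent[ik] <- .quantile_at(v * pk, pa$rate, pa$theta, pa$gamma)
    }
    cens <- if (config$censoring == "fixed") rep(config$study_years, n) else
      stats::runif(n, 0, config$study_years)
    obs <- pmax(pmin(latent, cens), 1e-6)
    event <- ifelse(latent <= cens, cause, 0L)
    dplyr::bind_cols(tibble::tibble(time = obs, event = as.integer(event)),
                     covs)
  })
}

#' Monte-Carlo validity summary of a cohort configuration
#'
#' Draws a large covariate sample and reports the worst plateau sum of the
#' two true cause models over it, plus the expected event mix under the
#' administrative censoring law.
#'
#' @param config A [cohort_config()].
#' @param n Monte-Carlo sample size.
#' @param seed RNG seed for the check.
#' @return A list with `worst_total` (max plateau sum), `pass`,
#'   `mean_cif4` (length-2: population-averaged true cumulative incidence of
#'   each cause at the study horizon) and `expected_observed` (length-2:
#'   expected fraction observed with each event under uniform censoring).
#' @export
validate_config <- function(config, n = 20000, seed = 1905) {
  stopifnot(inherits(config, "cohort_config"))
  covs <- draw_covariates(config, n = n, seed = seed)
  X <- .truth_design(config, covs)
  p1 <- cause_plateau(X, config$truth$cause1)
  p2 <- cause_plateau(X, config$truth$cause2)
  L <- config$study_years
  # Gauss-Legendre on (0, L) for the expected observed-event fraction
  # E_C F_k(C | x) with C ~ U(0, L)
  gl <- .gauss_legendre(20, 0, L)
  expf <- function(cm) {
    pa <- .params_at(X, cm)
    Ft <- vapply(gl$nodes, function(tt)
      mean(.cdf_at(tt, pa$rate, pa$theta, pa$gamma)), numeric(1))
    sum(gl$weights * Ft) / L
  }
  cif4 <- function(cm) {
    pa <- .params_at(X, cm)
    mean(.cdf_at(L, pa$rate, pa$theta, pa$gamma))
  }
  list(worst_total = max(p1 + p2), pass = max(p1 + p2) <= 1,
       mean_cif4 = c(cif4(config$truth$cause1), cif4(config$truth$cause2)),
       expected_observed = c(expf(config$truth$cause1),
                             expf(config$truth$cause2)))
}

# nodes/weights of Gauss-Legendre quadrature on (a, b)
.gauss_legendre <- function(n, a, b) {
  # Golub-Welsch from the Jacobi matrix of Legendre polynomials
  i <- seq_len(n - 1)
  bsub <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- bsub
  J[cbind(i + 1, i)] <- bsub
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}
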