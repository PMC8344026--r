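# A cause model couples baseline Gompertz parameters with a log-linear
# covariate effect on the rate: lambda(x) = lambda * exp(x'beta).  Ratios
# exp(beta) are the sub-hazard ratios reported for competing-risks data.

#' Cause model: baseline Gompertz plus covariate effects on the rate
#'
#' Covariates act multiplicatively on the rate parameter,
#' \eqn{\lambda(x) = \lambda \exp(x^\top \beta)}, leaving the power
#' \eqn{\theta} and shape \eqn{\gamma} covariate-free, so that each
#' covariate carries a single sub-hazard ratio \eqn{e^\beta} for the cause.
#'
#' @param params A [gomp_params()] baseline.
#' @param beta Named numeric vector of coefficients (log sub-hazard-ratio
#'   scale), one entry per covariate; may be empty for an intercept-only
#'   cause.
#'
#' @return An object of class `cause_model`.
#' @examples
#' cm <- cause_model(gomp_params(1.2, -0.4, 0.25), beta = c(age = 0.02))
#' cause_cdf(4, x = c(age = 60), cm)
#' @export
cause_model <- function(params, beta = numeric(0)) {
  .check_gomp(params)
  beta <- .named_numeric(beta)
  structure(list(params = params, beta = beta), class = "cause_model")
}

.named_numeric <- function(beta) {
  if (length(beta) == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(beta)) || any(names(beta) == "")) {
    stop("`beta` must be a fully named numeric vector.", call. = FALSE)
  }
  stats::setNames(as.numeric(beta), names(beta))
}

#' @export
print.cause_model <- function(x, ...) {
  cat("<cause_model>\n  baseline: ")
  print(x$params)
  if (length(x$beta)) {
    cat("  coefficients (log S-HR):\n")
    print(x$beta)
  } else cat("  intercept-only (no covariates)\n")
  invisible(x)
}

# covariate profile x -> per-subject gomp rate multiplier
.lin_pred <- function(x, cm) {
  if (length(cm$beta) == 0) return(rep(0, max(1L, NROW(x))))
  X <- .as_design(x, names(cm$beta))
  drop(X %*% cm$beta)
}

# Accept a named vector (one profile) or a matrix/data.frame with the
# model's covariate columns.
.as_design <- function(x, nm) {
  if (is.null(dim(x))) {
    if (is.null(names(x))) {
      if (length(x) != length(nm)) {
        stop("covariate vector has length ", length(x), ", expected ",
             length(nm), ".", call. = FALSE)
      }
      names(x) <- nm
    }
    x <- matrix(unlist(x[nm]), nrow = 1, dimnames = list(NULL, nm))
  } else {
    x <- as.matrix(as.data.frame(x)[, nm, drop = FALSE])
  }
  if (any(!is.finite(x))) stop("covariates must be finite.", call. = FALSE)
  x
}

.params_at <- function(x, cm) {
  eta <- .lin_pred(x, cm)
  list(theta = cm$params$theta, gamma = cm$params$gamma,
       rate = cm$params$rate * exp(eta))
}

# vectorized over subjects: t and rate may both be vectors
.cdf_at <- function(t, rate, theta, gamma) {
  G <- if (abs(gamma) < .GAMMA_EPS) rate * t else (rate / gamma) * expm1(gamma * t)
  (-expm1(-G))^theta
}

.logpdf_at <- function(t, rate, theta, gamma) {
  G <- if (abs(gamma) < .GAMMA_EPS) rate * t else (rate / gamma) * expm1(gamma * t)
  base <- log(theta) + log(rate) + gamma * t - G
  if (theta == 1) return(base)
  log1F <- ifelse(G == 0, -Inf, log(-expm1(-G)))
  base + (theta - 1) * log1F
}

.plateau_at <- function(rate, theta, gamma) {
  if (gamma >= 0) return(rep(1, length(rate)))
  (-expm1(rate / gamma))^theta
}

#' Cumulative incidence function of one cause at a covariate profile
#'
#' The model's sub-distribution function for the cause:
#' the baseline Gompertz CDF with the rate scaled by \eqn{\exp(x^\top\beta)}.
#'
#' @param t Times (years), each \eqn{\ge 0}.
#' @param x Named covariate vector (one profile), or a data frame / matrix of
#'   profiles with the model's covariate columns (then `t` must have length 1
#'   or match its row count).
#' @param cm A [cause_model()].
#' @return Cumulative incidence probabilities.
#' @export
cause_cdf <- function(t, x, cm) {
  .check_time(t)
  pa <- .params_at(x, cm)
  .cdf_at(t, pa$rate, pa$theta, pa$gamma)
}

#' @rdname cause_cdf
#' @export
cause_pdf <- function(t, x, cm) {
  .check_time(t)
  pa <- .params_at(x, cm)
  exp(.logpdf_at(t, pa$rate, pa$theta, pa$gamma))
}

#' Plateau of one cause's sub-distribution at covariate profiles
#'
#' @inheritParams cause_cdf
#' @return The limiting cumulative incidence \eqn{F_k(\infty \mid x)}.
#' @export
cause_plateau <- function(x, cm) {
  pa <- .params_at(x, cm)
  .plateau_at(pa$rate, pa$theta, pa$gamma)
}

#' Overall (event-free) survival under two competing causes
#'
#' \eqn{S(t\mid x) = 1 - F_1(t\mid x) - F_2(t\mid x)}.  Errors if the two
#' sub-distributions sum above 1 at any requested time, which signals an
#' invalid parameter/covariate combination.
#'
#' @inheritParams cause_cdf
#' @param cm1,cm2 The [cause_model()]s of the two competing events.
#' @return Survival probabilities in `[0, 1]`.
#' @export
overall_survival <- function(t, x, cm1, cm2) {
  F1 <- cause_cdf(t, x, cm1)
  F2 <- cause_cdf(t, x, cm2)
  tot <- F1 + F2
  if (any(tot > 1 + 1e-12)) {
    stop("F1 + F2 exceeds 1 (max ", format(max(tot)),
         "); the cause models are not jointly valid at this profile.",
         call. = FALSE)
  }
  pmax(1 - tot, 0)
}

#' Joint validity of two improper sub-distributions over a design
#'
#' Two sub-distribution plateaus must sum to at most 1 at every covariate
#' profile for the pair to describe one cohort (the residual is the
#' event-free mass).  Reports the worst case over the rows of `X` and a
#' pass/fail flag; failure is a reported state, not an error.
#'
#' @param cm1,cm2 [cause_model()]s.
#' @param X Covariate data frame or matrix (may have zero rows, in which
#'   case only the baseline profile is checked).
#' @return A list with `total` (worst-case plateau sum), `pass`, and
#'   `worst_row` (row index of the worst profile; `NA` for the baseline
#'   check).
#' @export
validity_check <- function(cm1, cm2, X = NULL) {
  if (is.null(X) || NROW(X) == 0) {
    tot <- gomp_plateau(cm1$params) + gomp_plateau(cm2$params)
    return(list(total = tot, pass = tot <= 1, worst_row = NA_integer_))
  }
  tot <- cause_plateau(X, cm1) + cause_plateau(X, cm2)
  i <- which.max(tot)
  list(total = tot[i], pass = tot[i] <= 1, worst_row = i)
}
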