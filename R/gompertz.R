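# Three-parameter (generalized) Gompertz distribution.
#
# F(t) = [1 - exp(-(lambda/gamma) (e^{gamma t} - 1))]^theta
#
# With gamma < 0 the distribution is improper: F(t) plateaus at
# [1 - exp(lambda/gamma)]^theta < 1.  The residual mass is the probability
# that the event never occurs, which is what lets one cause's
# sub-distribution leave room for a competing cause.

# switch to the gamma -> 0 series limit below this to avoid cancellation
# in (e^{gamma t} - 1)/gamma
.GAMMA_EPS <- 1e-8

#' Three-parameter Gompertz parameters
#'
#' Bundles the parameters of the generalized Gompertz distribution
#' \deqn{F(t) = \left[1 - \exp\!\big(-\tfrac{\lambda}{\gamma}(e^{\gamma t} - 1)\big)\right]^{\theta}.}
#' When `gamma < 0` the distribution is *improper*: the cumulative
#' distribution function plateaus at \eqn{[1 - e^{\lambda/\gamma}]^\theta < 1}
#' and the remaining mass is the probability the event never occurs.  This
#' improper regime is the building block for sub-distribution (cumulative
#' incidence) modelling of competing events.
#'
#' @param theta Power exponent \eqn{\theta > 0} (dimensionless).
#' @param gamma Gompertz shape \eqn{\gamma} (per year); any real value.
#'   Negative values give a plateau (cure) mass.
#' @param rate Rate \eqn{\lambda > 0} (per year).
#'
#' @return An object of class `gomp_params`.
#' @examples
#' p <- gomp_params(theta = 2, gamma = -0.5, rate = 1)
#' gomp_plateau(p)
#' gomp_cdf(c(0, 1, 5, 50), p)
#' @export
gomp_params <- function(theta, gamma, rate) {
  stopifnot(is.numeric(theta), is.numeric(gamma), is.numeric(rate),
            length(theta) == 1L, length(gamma) == 1L, length(rate) == 1L)
  if (!is.finite(theta) || theta <= 0) {
    stop("`theta` must be finite and > 0, got ", theta, call. = FALSE)
  }
  if (!is.finite(rate) || rate <= 0) {
    stop("`rate` must be finite and > 0, got ", rate, call. = FALSE)
  }
  if (!is.finite(gamma)) stop("`gamma` must be finite.", call. = FALSE)
  structure(list(theta = theta, gamma = gamma, rate = rate),
            class = "gomp_params")
}

#' @export
print.gomp_params <- function(x, ...) {
  cat(sprintf("<gomp_params> theta = %g, gamma = %g /yr, rate = %g /yr\n",
              x$theta, x$gamma, x$rate))
  cat(sprintf("  plateau = %.6g%s\n", gomp_plateau(x),
              if (x$gamma < 0) " (improper)" else ""))
  invisible(x)
}

.check_gomp <- function(p) {
  if (!inherits(p, "gomp_params")) stop("`p` must be a `gomp_params` object.",
                                        call. = FALSE)
  p
}

.check_time <- function(t) {
  if (any(!is.finite(t) | t < 0)) {
    stop("times must be finite and >= 0.", call. = FALSE)
  }
  t
}

# Integrated "rate" G(t) = (lambda/gamma)(e^{gamma t} - 1), with the
# gamma -> 0 limit lambda * t; F(t) = (1 - exp(-G))^theta.
.gomp_G <- function(t, gamma, rate) {
  if (abs(gamma) < .GAMMA_EPS) rate * t else (rate / gamma) * expm1(gamma * t)
}

#' Distribution function of the three-parameter Gompertz
#'
#' @param t Vector of times (years), each \eqn{\ge 0}.
#' @param p A [gomp_params()] object.
#' @return `F(t)`, bounded above by [gomp_plateau()].
#' @export
gomp_cdf <- function(t, p) {
  .check_gomp(p); .check_time(t)
  G <- .gomp_G(t, p$gamma, p$rate)
  (-expm1(-G))^p$theta
}

#' Density of the three-parameter Gompertz
#'
#' `gomp_pdf()` returns the density (per year); `gomp_logpdf()` its logarithm,
#' computed on the log scale throughout for use in likelihoods.
#'
#' @inheritParams gomp_cdf
#' @return Density values \eqn{f(t) \ge 0}.
#' @export
gomp_pdf <- function(t, p) {
  exp(gomp_logpdf(t, p))
}

#' @rdname gomp_pdf
#' @export
gomp_logpdf <- function(t, p) {
  .check_gomp(p); .check_time(t)
  G <- .gomp_G(t, p$gamma, p$rate)
  # log f = log(theta) + log(lambda) + gamma t - G + (theta - 1) log(1 - e^{-G})
  base <- log(p$theta) + log(p$rate) + p$gamma * t - G
  if (p$theta == 1) return(base)
  log1F <- ifelse(G == 0, -Inf, log(-expm1(-G)))  # log(1 - e^{-G})
  base + (p$theta - 1) * log1F
}

#' Plateau (cure) mass of a Gompertz sub-distribution
#'
#' The limit of the distribution function as \eqn{t \to \infty}: 1 when
#' \eqn{\gamma \ge 0} (proper distribution), \eqn{[1 - e^{\lambda/\gamma}]^\theta}
#' when \eqn{\gamma < 0}.
#'
#' @inheritParams gomp_cdf
#' @return A probability in `(0, 1]`.
#' @export
gomp_plateau <- function(p) {
  .check_gomp(p)
  if (p$gamma >= 0) return(1)
  (-expm1(p$rate / p$gamma))^p$theta
}

#' Quantile function of the three-parameter Gompertz
#'
#' Closed-form inverse of [gomp_cdf()].  Defined only for probabilities
#' strictly below the plateau; an improper distribution has no finite
#' quantile at or above its plateau mass.
#'
#' @param u Vector of probabilities, each in `[0, plateau)`.
#' @inheritParams gomp_cdf
#' @return Times (years) with `gomp_cdf(gomp_quantile(u, p), p) == u`.
#' @export
gomp_quantile <- function(u, p) {
  .check_gomp(p)
  if (any(!is.finite(u) | u < 0)) stop("`u` must be in [0, plateau).",
                                       call. = FALSE)
  pl <- gomp_plateau(p)
  if (any(u >= pl)) {
    stop("`u` must be < plateau(p) = ", format(pl),
         "; no finite quantile exists at or above the plateau.", call. = FALSE)
  }
  q <- -log1p(-u^(1 / p$theta))          # G(t) at the quantile
  if (abs(p$gamma) < .GAMMA_EPS) {
    q / p$rate
  } else {
    log1p(p$gamma * q / p$rate) / p$gamma
  }
}

#' Draw event times from a Gompertz sub-distribution
#'
#' Inverse-transform sampling.  With probability `1 - gomp_plateau(p)` the
#' event never occurs; such draws are returned as `Inf` (a distinguished
#' "never" value, so they can not be confused with any finite follow-up
#' time under censoring comparisons).
#'
#' @param n Number of draws.
#' @inheritParams gomp_cdf
#' @return Numeric vector of length `n`: finite times or `Inf`.
#' @export
gomp_sample <- function(n, p) {
  .check_gomp(p)
  stopifnot(length(n) == 1L, n >= 0)
  if (n == 0) return(numeric(0))
  u <- stats::runif(n)
  pl <- gomp_plateau(p)
  out <- rep(Inf, n)
  fin <- u < pl
  out[fin] <- gomp_quantile(u[fin], p)
  out
}

#' Sub-distribution hazard
#'
#' The hazard of the improper distribution, \eqn{f(t) / (1 - F(t))} — the
#' quantity whose covariate ratios are reported as sub-hazard ratios (S-HR).
#'
#' @inheritParams gomp_cdf
#' @return Hazard values (per year).
#' @export
gomp_subhazard <- function(t, p) {
  Ft <- gomp_cdf(t, p)
  if (any(Ft >= 1)) stop("sub-distribution hazard undefined where F(t) = 1.",
                         call. = FALSE)
  gomp_pdf(t, p) / (1 - Ft)
}
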