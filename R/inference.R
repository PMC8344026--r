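# Wald inference on the transformed scale; ratio-scale intervals are the
# exponential of the beta interval endpoints (endpoint transform, not a
# delta-method SE on the ratio scale, so the interval keeps its level).

.beta_entries <- function(fit) {
  out <- list()
  for (k in fit$causes) {
    ck <- paste0("c", k)
    ix <- fit$skeleton$idx[[ck]]$beta
    if (length(ix)) {
      out[[ck]] <- tibble::tibble(
        cause = fit$cause_labels[k],
        term = fit$coef_names[[ck]],
        par_name = fit$skeleton$names[ix],
        index = ix
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Wald confidence intervals for sub-hazard-ratio coefficients
#'
#' For each requested coefficient returns the Wald interval
#' \eqn{\hat\beta \pm z_{(1+level)/2}\,SE} on the log scale, the sub-hazard
#' ratio interval obtained by exponentiating its endpoints, and the
#' two-sided Wald p-value.
#'
#' @param fit A converged [crisk_fit()] with available covariance.
#' @param term Coefficient name(s) (as in `tidy(fit)`), optionally prefixed
#'   `"c1:"`/`"c2:"`; `NULL` for all coefficients.
#' @param level Confidence level in (0, 1).
#' @return A tibble with `cause`, `term`, `estimate` (log scale),
#'   `std.error`, `conf.low`, `conf.high`, `shr`, `shr.low`, `shr.high`,
#'   `p.value`, `level`.
#' @export
wald_ci <- function(fit, term = NULL, level = 0.95) {
  stopifnot(inherits(fit, "crisk_fit"), level > 0, level < 1)
  if (!fit$converged) {
    stop("fit did not converge; Wald intervals unavailable.", call. = FALSE)
  }
  if (all(!is.finite(fit$vcov))) {
    stop("covariance unavailable for this fit.", call. = FALSE)
  }
  be <- .beta_entries(fit)
  if (nrow(be) == 0) stop("fit has no covariate coefficients.", call. = FALSE)
  if (!is.null(term)) {
    keep <- be$term %in% term | be$par_name %in% term
    if (!any(keep)) stop("unknown coefficient name(s): ",
                         paste(setdiff(term, c(be$term, be$par_name)),
                               collapse = ", "), call. = FALSE)
    be <- be[keep, , drop = FALSE]
  }
  est <- fit$estimates[be$index]
  se <- sqrt(diag(fit$vcov)[be$index])
  z <- stats::qnorm((1 + level) / 2)
  lo <- est - z * se
  hi <- est + z * se
  tibble::tibble(
    cause = be$cause, term = be$term,
    estimate = unname(est), std.error = unname(se),
    conf.low = unname(lo), conf.high = unname(hi),
    shr = exp(unname(est)), shr.low = exp(unname(lo)),
    shr.high = exp(unname(hi)),
    p.value = 2 * stats::pnorm(-abs(unname(est) / unname(se))),
    level = level
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a competing-risks fit
#'
#' One row per estimated parameter.  Baseline rows carry the transformed
#' parameters (`log(theta)`, `gamma`, `log(rate)`); coefficient rows carry
#' \eqn{\hat\beta} with Wald statistics, and `exponentiate = TRUE` reports
#' them as sub-hazard ratios.
#'
#' @param x A [crisk_fit()].
#' @param exponentiate Report coefficient rows (and their intervals) as
#'   sub-hazard ratios.
#' @param conf.int,conf.level Add Wald confidence bounds.
#' @param ... Unused.
#' @return A tibble with columns `cause`, `term`, `type`, `estimate`,
#'   `std.error`, `statistic`, `p.value` (and `conf.low`/`conf.high`).
#' @method tidy crisk_fit
#' @export
tidy.crisk_fit <- function(x, exponentiate = FALSE, conf.int = FALSE,
                           conf.level = 0.95, ...) {
  se_all <- sqrt(diag(x$vcov))
  rows <- list()
  for (k in x$causes) {
    ck <- paste0("c", k)
    ib <- x$skeleton$idx[[ck]]$base
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cause = x$cause_labels[k],
      term = c("log(theta)", "gamma", "log(rate)"),
      type = "baseline",
      estimate = unname(x$estimates[ib]),
      std.error = unname(se_all[ib]),
      statistic = NA_real_, p.value = NA_real_
    )
    ix <- x$skeleton$idx[[ck]]$beta
    if (length(ix)) {
      est <- unname(x$estimates[ix]); se <- unname(se_all[ix])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cause = x$cause_labels[k], term = x$coef_names[[ck]],
        type = "coefficient", estimate = est, std.error = se,
        statistic = est / se, p.value = 2 * stats::pnorm(-abs(est / se))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (conf.int) {
    z <- stats::qnorm((1 + conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  if (exponentiate) {
    cf <- out$type == "coefficient"
    out$estimate[cf] <- exp(out$estimate[cf])
    if (conf.int) {
      out$conf.low[cf] <- exp(out$conf.low[cf])
      out$conf.high[cf] <- exp(out$conf.high[cf])
    }
  }
  out
}

#' Glance at a competing-risks fit
#'
#' @param x A [crisk_fit()].
#' @param ... Unused.
#' @return A one-row tibble with fit-level summaries.
#' @method glance crisk_fit
#' @export
glance.crisk_fit <- function(x, ...) {
  npar <- length(x$estimates)
  tibble::tibble(
    logLik = x$loglik, AIC = -2 * x$loglik + 2 * npar,
    BIC = -2 * x$loglik + log(x$n_used) * npar,
    nobs = x$n_used, n_event1 = unname(x$n_events[1]),
    n_event2 = unname(x$n_events[2]), npar = npar,
    converged = x$converged, grad_norm = x$grad_norm
  )
}

# reference-coded factor structure of one cause's design, for table layout
.term_layout <- function(fit, k) {
  ck <- paste0("c", k)
  xlev <- fit$designs[[ck]]$xlevels
  terms <- fit$coef_names[[ck]]
  rows <- list()
  consumed <- character(0)
  for (v in names(xlev)) {
    lv <- xlev[[v]]
    coefs <- paste0(v, lv[-1])
    rows[[v]] <- tibble::tibble(
      variable = v, level = lv,
      term = c(NA_character_, coefs),
      reference = c(TRUE, rep(FALSE, length(lv) - 1L))
    )
    consumed <- c(consumed, coefs)
  }
  cont <- setdiff(terms, consumed)
  for (v in cont) {
    rows[[v]] <- tibble::tibble(variable = v, level = NA_character_,
                                term = v, reference = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Sub-hazard-ratio table with confidence intervals at several levels
#'
#' One row per coefficient per modeled cause, with the sub-hazard ratio,
#' a Wald confidence interval per requested level, and the two-sided Wald
#' p-value.  Reference categories of factor covariates are rendered as
#' their own rows with S-HR fixed at 1 and no interval, the convention of
#' clinical prognostic-factor tables.
#'
#' @param fit A converged [crisk_fit()].
#' @param levels Confidence levels; the default pairs a 75% interval
#'   (univariate screening convention) with a 90% interval (multivariate
#'   reporting convention).
#' @return A tibble with `cause`, `variable`, `level`, `reference`, `shr`,
#'   `p.value`, numeric interval columns `conf.low.<pct>`/`conf.high.<pct>`,
#'   and formatted `shr_ci_<pct>` strings.
#' @export
shr_table <- function(fit, levels = c(0.75, 0.90)) {
  stopifnot(inherits(fit, "crisk_fit"))
  cis <- lapply(levels, function(l) wald_ci(fit, level = l))
  base <- cis[[1]][, c("cause", "term", "shr", "p.value")]
  out <- list()
  for (k in fit$causes) {
    if (length(fit$coef_names[[paste0("c", k)]]) == 0) next
    lay <- .term_layout(fit, k)
    lay$cause <- fit$cause_labels[k]
    lay <- dplyr::left_join(lay, base, by = c("cause", "term"))
    lay$shr[lay$reference] <- 1
    out[[length(out) + 1L]] <- lay
  }
  out <- dplyr::bind_rows(out)
  for (i in seq_along(levels)) {
    pct <- format(100 * levels[i])
    ci <- cis[[i]][, c("cause", "term", "shr.low", "shr.high")]
    names(ci) <- c("cause", "term", paste0("conf.low.", pct),
                   paste0("conf.high.", pct))
    out <- dplyr::left_join(out, ci, by = c("cause", "term"))
    out[[paste0("shr_ci_", pct)]] <- ifelse(
      out$reference, "1",
      sprintf("%.2f (%.2f-%.2f)", out$shr,
              out[[paste0("conf.low.", pct)]],
              out[[paste0("conf.high.", pct)]]))
  }
  dplyr::relocate(out, "cause", "variable", "level", "term", "reference",
                  "shr", "p.value")
}
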