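# Model-based cumulative incidence curves from a fitted model.

# expand a one-row data frame of original variables to the model.matrix row
# used by cause k; NULL -> baseline profile (reference categories, zero
# continuous covariates)
.profile_row <- function(fit, k, newdata) {
  ck <- paste0("c", k)
  nm <- fit$coef_names[[ck]]
  if (length(nm) == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.null(newdata)) return(stats::setNames(numeric(length(nm)), nm))
  tt <- fit$designs[[ck]]$terms
  mf <- stats::model.frame(tt, newdata, xlev = fit$designs[[ck]]$xlevels)
  X <- stats::model.matrix(tt, mf)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  stats::setNames(X[1, nm], nm)
}

#' Model-based cumulative incidence curves
#'
#' Evaluates each modeled cause's fitted sub-distribution function on a time
#' grid at a covariate profile.  Curves are non-decreasing from 0 and their
#' sum never exceeds 1; an invalid profile (plateaus summing above 1) is an
#' error.
#'
#' @param fit A converged [crisk_fit()].
#' @param newdata Optional one-row data frame giving the covariate profile
#'   on the original variable scale; default is the baseline profile
#'   (reference categories, continuous covariates at 0).
#' @param times Time grid (years).
#' @return A tibble with columns `time`, `cause`, `cif`.
#' @export
cif_curve <- function(fit, newdata = NULL, times = seq(0, 4, by = 0.1)) {
  stopifnot(inherits(fit, "crisk_fit"))
  if (!fit$converged) stop("fit did not converge.", call. = FALSE)
  .check_time(times)
  profs <- lapply(fit$causes, function(k) .profile_row(fit, k, newdata))
  names(profs) <- paste0("c", fit$causes)
  if (length(fit$causes) == 2) {
    pl <- sum(vapply(fit$causes, function(k) {
      ck <- paste0("c", k)
      x <- profs[[ck]]
      cause_plateau(matrix(x, nrow = 1, dimnames = list(NULL, names(x))),
                    fit$models[[ck]])
    }, numeric(1)))
    if (pl > 1 + 1e-12) {
      stop("sub-distribution plateaus sum to ", format(pl, digits = 4),
           " > 1 at this profile; cumulative incidence is not defined.",
           call. = FALSE)
    }
  }
  out <- lapply(fit$causes, function(k) {
    ck <- paste0("c", k)
    x <- profs[[ck]]
    Xr <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
    pa <- .params_at(Xr, fit$models[[ck]])
    tibble::tibble(time = times,
                   cause = fit$cause_labels[k],
                   cif = .cdf_at(times, pa$rate, pa$theta, pa$gamma))
  })
  dplyr::bind_rows(out)
}
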