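# Joint likelihood for two competing events with Gompertz sub-distributions.
#
# Each subject contributes
#   event = 1:  log f1(t | x)
#   event = 2:  log f2(t | x)
#   event = 0:  log(1 - F1(t | x) - F2(t | x))
# so both causes enter every subject's term: the model treats the event of
# interest and the competing event simultaneously rather than censoring one
# for the other.

# smooth penalty floor for the censored term: below .S_EPS the log is
# continued linearly so the objective stays finite and decreasing in -S
.S_EPS <- 1e-10

.check_records <- function(data, need_cov = character(0)) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop("`data` must be a nonempty data frame.", call. = FALSE)
  }
  if (!all(c("time", "event") %in% names(data))) {
    stop("`data` must have `time` and `event` columns.", call. = FALSE)
  }
  if (any(!is.finite(data$time)) || any(data$time <= 0)) {
    stop("all follow-up times must be finite and > 0.", call. = FALSE)
  }
  if (!all(data$event %in% c(0L, 1L, 2L))) {
    stop("`event` must be coded 0 (censored), 1, or 2.", call. = FALSE)
  }
  for (v in need_cov) {
    if (!v %in% names(data)) stop("covariate `", v, "` not found in data.",
                                  call. = FALSE)
    if (is.numeric(data[[v]]) && any(!is.finite(data[[v]]))) {
      stop("covariate `", v, "` contains non-finite values.", call. = FALSE)
    }
  }
  invisible(data)
}

# log of the censored contribution with a linear continuation below eps
.log_surv_penalized <- function(S, eps = .S_EPS) {
  ifelse(S > eps, log(pmax(S, eps)), log(eps) + (S - eps) / eps)
}

# Analytic score of the joint log-likelihood on the transformed scale
# (a = log theta, gamma, b = log lambda, beta), one block per cause.
# For an event of cause k the contribution is d log f_k; for a censored
# record it is -dF_k / max(S, eps) (the derivative of the penalized
# censored term).  Returns the gradient blocks as a list per cause.
.score_blocks <- function(t, ev, X1, X2, cm1, cm2) {
  S_eps <- .S_EPS
  n <- length(t)
  comp <- function(cm, X) {
    th <- cm$params$theta; ga <- cm$params$gamma
    r <- cm$params$rate * if (length(cm$beta)) exp(drop(X %*% cm$beta)) else rep(1, n)
    if (abs(ga) < .GAMMA_EPS) {
      G <- r * t
      dGdg <- r * t^2 / 2
      egt <- 1
    } else {
      egt <- exp(ga * t)
      G <- (r / ga) * expm1(ga * t)
      dGdg <- (r * t * egt - G) / ga
    }
    E <- -expm1(-G)
    eG <- exp(-G)
    list(th = th, r = r, G = G, dGdg = dGdg, E = E, eG = eG)
  }
  c1 <- comp(cm1, X1)
  c2 <- if (!is.null(cm2)) comp(cm2, X2) else NULL
  F1 <- c1$E^c1$th
  F2 <- if (!is.null(c2)) c2$E^c2$th else 0
  S <- 1 - F1 - F2
  wS <- 1 / pmax(S, S_eps)

  block <- function(cc, X, k, Fk) {
    th <- cc$th
    gb <- numeric(3 + NCOL(X))
    iev <- ev == k
    i0 <- ev == 0L
    # event contributions
    if (any(iev)) {
      ratio <- (th - 1) * cc$eG[iev] / cc$E[iev]
      brk <- 1 + cc$G[iev] * (ratio - 1)
      gb[1] <- sum(1 + th * log(cc$E[iev]))
      gb[2] <- sum(t[iev] + cc$dGdg[iev] * (ratio - 1))
      gb[3] <- sum(brk)
      if (NCOL(X)) gb[-(1:3)] <- colSums(X[iev, , drop = FALSE] * brk)
    }
    # censored contributions
    if (any(i0)) {
      w <- wS[i0]
      Fk0 <- Fk[i0]
      dFda <- Fk0 * th * log(cc$E[i0])
      core <- th * cc$E[i0]^(th - 1) * cc$eG[i0]
      dFdg <- core * cc$dGdg[i0]
      dFdb <- core * cc$G[i0]
      gb[1] <- gb[1] - sum(w * dFda)
      gb[2] <- gb[2] - sum(w * dFdg)
      gb[3] <- gb[3] - sum(w * dFdb)
      if (NCOL(X)) gb[-(1:3)] <- gb[-(1:3)] -
          colSums(X[i0, , drop = FALSE] * (w * dFdb))
    }
    gb
  }
  out <- list(c1 = block(c1, X1, 1L, F1))
  if (!is.null(c2)) out$c2 <- block(c2, X2, 2L, F2)
  out
}

#' Joint log-likelihood of a two-cause competing-risks model
#'
#' Sums, over subjects, the log sub-density of the observed cause for events
#' and the log of the event-free probability \eqn{1 - F_1 - F_2} for censored
#' records.  When the event-free probability falls below `1e-10` at a
#' censored point (an invalid parameter/covariate combination) the log is
#' continued linearly, which keeps optimization well-defined without hard
#' constraints.
#'
#' @param data Data frame with columns `time` (years, > 0), `event`
#'   (0 censored / 1 / 2), and the covariates named in the models' `beta`s.
#' @param cm1,cm2 [cause_model()]s for causes 1 and 2.  `cm2 = NULL` fits a
#'   single-cause model (only permitted when `data` has no cause-2 events).
#' @return The log-likelihood (scalar).
#' @export
crisk_loglik <- function(data, cm1, cm2 = NULL) {
  need <- unique(c(names(cm1$beta), if (!is.null(cm2)) names(cm2$beta)))
  .check_records(data, need)
  if (is.null(cm2) && any(data$event == 2L)) {
    stop("data contains cause-2 events but no cause-2 model was given.",
         call. = FALSE)
  }
  t <- data$time
  ev <- data$event
  pa1 <- .params_at(data, cm1)
  F1 <- .cdf_at(t, pa1$rate, pa1$theta, pa1$gamma)
  if (!is.null(cm2)) {
    pa2 <- .params_at(data, cm2)
    F2 <- .cdf_at(t, pa2$rate, pa2$theta, pa2$gamma)
  } else F2 <- rep(0, length(t))
  ll <- numeric(length(t))
  i1 <- ev == 1L; i2 <- ev == 2L; i0 <- ev == 0L
  if (any(i1)) ll[i1] <- .logpdf_at(t[i1], pa1$rate[i1], pa1$theta, pa1$gamma)
  if (any(i2)) ll[i2] <- .logpdf_at(t[i2], pa2$rate[i2], pa2$theta, pa2$gamma)
  if (any(i0)) ll[i0] <- .log_surv_penalized(1 - F1[i0] - F2[i0])
  sum(ll)
}
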