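# Maximum-likelihood fitting of the two-cause Gompertz sub-distribution
# model.  Optimization runs on a transformed scale (log theta, gamma,
# log lambda, beta) so every iterate is a valid parameter set; a quasi-Newton
# search with multistart (analytic score) is followed by a Newton polish
# whose Hessian -- the central-difference jacobian of the score -- provides
# the observed information and hence the Wald covariance.

#' Optimizer settings for [crisk_fit()]
#'
#' @param multistart Number of starts: the first uses moment-style initial
#'   values (event-rate-based \eqn{\lambda}, \eqn{\gamma = -0.1},
#'   \eqn{\theta = 1}, \eqn{\beta = 0}); the rest jitter them.
#' @param jitter_sd Standard deviation of the Gaussian jitter applied to the
#'   transformed starting values.
#' @param seed RNG seed for the jitter, so fits are reproducible.
#' @param maxit Maximum BFGS iterations per start.
#' @param reltol Relative convergence tolerance on the objective.
#' @param hessian_step Central-difference step (transformed scale) for the
#'   observed-information matrix.
#' @param polish_iter Maximum Newton polish iterations after BFGS.
#' @param grad_tol Gradient-norm target (transformed scale) for the polish.
#' @return A list of settings.
#' @export
crisk_control <- function(multistart = 5, jitter_sd = 0.5, seed = 101,
                          maxit = 1000, reltol = 1e-8, hessian_step = 1e-5,
                          polish_iter = 10, grad_tol = 1e-6) {
  list(multistart = multistart, jitter_sd = jitter_sd, seed = seed,
       maxit = maxit, reltol = reltol, hessian_step = hessian_step,
       polish_iter = polish_iter, grad_tol = grad_tol)
}

# ---- parameter packing -----------------------------------------------------

# layout: for each modeled cause k, (ltheta, gamma, lrate, beta_1..beta_pk)
.par_skeleton <- function(causes, coef_names) {
  idx <- list(); nm <- character(0); off <- 0L
  for (k in causes) {
    ck <- paste0("c", k)
    p <- length(coef_names[[ck]])
    idx[[ck]] <- list(base = off + 1:3, beta = if (p) off + 3L + seq_len(p) else integer(0))
    nm <- c(nm, paste0(ck, ":", c("ltheta", "gamma", "lrate")),
            if (p) paste0(ck, ":", coef_names[[ck]]))
    off <- off + 3L + p
  }
  list(idx = idx, names = nm, length = off)
}

.unpack <- function(par, skel, causes, coef_names) {
  out <- list()
  for (k in causes) {
    ck <- paste0("c", k)
    b <- par[skel$idx[[ck]]$base]
    beta <- par[skel$idx[[ck]]$beta]
    names(beta) <- coef_names[[ck]]
    out[[ck]] <- cause_model(gomp_params(exp(b[1]), b[2], exp(b[3])), beta)
  }
  out
}

# ---- numerical derivatives -------------------------------------------------

.num_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h
    g[i] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  g
}

.num_jac <- function(g, x, h = 1e-5) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- h
    J[, i] <- (g(x + e) - g(x - e)) / (2 * h)
  }
  J
}

# ---- design construction ---------------------------------------------------

# expand a one-sided formula against data; returns the design matrix (no
# intercept column) plus factor-level bookkeeping for reporting
.build_design <- function(formula, data) {
  if (is.null(formula)) formula <- ~1
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  X <- stats::model.matrix(formula, mf)
  xlev <- stats::.getXlevels(stats::terms(formula), mf)
  keep <- colnames(X) != "(Intercept)"
  list(X = X[, keep, drop = FALSE], xlevels = xlev,
       terms = stats::terms(formula))
}

# ---- main fitter -----------------------------------------------------------

#' Fit the two-cause Gompertz competing-risks regression
#'
#' Maximizes the joint likelihood of [crisk_loglik()] over the transformed
#' parameters \eqn{(\log\theta_k, \gamma_k, \log\lambda_k, \beta_k)} of the
#' modeled causes.  Covariates are specified per cause as one-sided
#' formulas; factors are expanded to reference-coded indicators.  Rows with
#' missing values in any used covariate are dropped (complete-case) with a
#' message.
#'
#' @param data Data frame with `time` (years, > 0), `event` (0/1/2), and
#'   covariates.
#' @param cause1,cause2 One-sided formulas giving the covariates acting on
#'   each cause's rate; `~ 1` for an intercept-only cause.
#' @param causes Integer vector of causes to model (default both present in
#'   the data).  A cause with zero events cannot be modeled.
#' @param cause_labels Labels used in output tables for causes 1 and 2.
#' @param control See [crisk_control()].
#'
#' @return An object of class `crisk_fit` with elements `estimates`
#'   (transformed scale), `vcov`, `loglik`, `converged`, `n_used`,
#'   `models` (per-cause [cause_model()]s at the optimum), and bookkeeping
#'   for [tidy()][generics::tidy], [shr_table()] and [cif_curve()].
#' @examples
#' cfg <- default_cohort_config(seed = 7)
#' coh <- simulate_cohort(cfg)
#' fit <- crisk_fit(coh, cause1 = ~ age, cause2 = ~ age)
#' shr_table(fit)
#' @export
crisk_fit <- function(data, cause1 = ~1, cause2 = ~1, causes = NULL,
                      cause_labels = c("death", "transplant"),
                      control = crisk_control()) {
  .check_records(data)
  if (is.null(causes)) causes <- c(1L, 2L)
  causes <- sort(unique(as.integer(causes)))
  stopifnot(all(causes %in% 1:2), length(causes) >= 1)
  if (length(causes) == 1 && any(data$event == setdiff(1:2, causes))) {
    stop("data contains events of an unmodeled cause; include it in `causes`.",
         call. = FALSE)
  }
  forms <- list(c1 = cause1, c2 = cause2)

  # complete-case on the used covariates
  used_vars <- unique(unlist(lapply(causes, function(k)
    all.vars(forms[[paste0("c", k)]]))))
  n0 <- nrow(data)
  if (length(used_vars)) {
    cc <- stats::complete.cases(data[, used_vars, drop = FALSE])
    data <- data[cc, , drop = FALSE]
    if (nrow(data) < n0) {
      message("dropped ", n0 - nrow(data),
              " record(s) with missing covariates (complete-case analysis)")
    }
  }
  .check_records(data)
  for (k in causes) {
    if (!any(data$event == k)) {
      stop("no events of cause ", k, " in data; cannot fit that cause.",
           call. = FALSE)
    }
  }

  designs <- list()
  coef_names <- list()
  for (k in causes) {
    ck <- paste0("c", k)
    designs[[ck]] <- .build_design(forms[[ck]], data)
    coef_names[[ck]] <- colnames(designs[[ck]]$X)
  }
  skel <- .par_skeleton(causes, coef_names)

  # augmented data: design columns bound on with their model.matrix names
  aug <- data[, c("time", "event")]
  for (k in causes) {
    ck <- paste0("c", k)
    X <- designs[[ck]]$X
    for (j in seq_len(ncol(X))) aug[[colnames(X)[j]]] <- X[, j]
  }

  negll <- function(par) {
    # wild line-search iterates can underflow exp(log theta) etc.
    if (any(!is.finite(par)) || any(abs(par) > 50)) return(1e10)
    cms <- .unpack(par, skel, causes, coef_names)
    ll <- crisk_loglik(aug, cm1 = if ("c1" %in% names(cms)) cms$c1 else cms$c2,
                       cm2 = if (length(causes) == 2) cms$c2 else NULL)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  # analytic score (negative), matching negll on the transformed scale
  gradnll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 50)) return(numeric(length(par)))
    cms <- .unpack(par, skel, causes, coef_names)
    g <- numeric(length(par))
    if (length(causes) == 2) {
      sb <- .score_blocks(aug$time, aug$event, designs$c1$X, designs$c2$X,
                          cms$c1, cms$c2)
      for (k in causes) {
        ck <- paste0("c", k)
        g[skel$idx[[ck]]$base] <- sb[[ck]][1:3]
        if (length(skel$idx[[ck]]$beta)) {
          g[skel$idx[[ck]]$beta] <- sb[[ck]][-(1:3)]
        }
      }
    } else {
      ck <- paste0("c", causes)
      sb <- .score_blocks(aug$time, aug$event, designs[[ck]]$X, NULL,
                          cms[[ck]], NULL)
      g[skel$idx[[ck]]$base] <- sb$c1[1:3]
      if (length(skel$idx[[ck]]$beta)) g[skel$idx[[ck]]$beta] <- sb$c1[-(1:3)]
    }
    -g
  }
  # single-cause fit of cause 2 alone: crisk_loglik treats the given model
  # as "cm1"; event codes must then be recoded 2 -> 1
  if (identical(causes, 2L)) {
    aug$event[aug$event == 2L] <- 1L
  }

  # moment-style starting values
  start <- numeric(skel$length)
  names(start) <- skel$names
  for (k in causes) {
    ck <- paste0("c", k)
    ev_k <- if (identical(causes, 2L)) 1L else k
    lam0 <- sum(aug$event == ev_k) / sum(aug$time)
    start[skel$idx[[ck]]$base] <- c(0, -0.1, log(lam0))
  }

  runs <- list()
  for (s in seq_len(control$multistart)) {
    st <- if (s == 1) start else
      withr::with_seed(control$seed + s, start +
                         stats::rnorm(length(start), sd = control$jitter_sd))
    opt <- tryCatch(
      stats::optim(st, negll, gr = gradnll, method = "BFGS",
                   control = list(maxit = control$maxit,
                                  reltol = control$reltol)),
      error = function(e) NULL)
    if (!is.null(opt)) runs[[length(runs) + 1L]] <- opt
  }
  if (!length(runs)) stop("all optimizer starts failed.", call. = FALSE)
  vals <- vapply(runs, function(r) r$value, numeric(1))
  best <- runs[[which.min(vals)]]
  par <- best$par
  converged <- best$convergence == 0

  # Newton polish toward a stationary point; the observed information is
  # the (symmetrized) central-difference jacobian of the analytic score
  hess <- function(p) {
    J <- .num_jac(gradnll, p, h = control$hessian_step)
    (J + t(J)) / 2
  }
  g <- gradnll(par)
  H <- NULL
  for (it in seq_len(control$polish_iter)) {
    if (sqrt(sum(g^2)) < control$grad_tol) break
    H <- hess(par)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    f0 <- negll(par)
    alpha <- 1
    repeat {
      cand <- par - alpha * step
      if (negll(cand) <= f0 || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    if (negll(cand) > f0) break
    par <- cand
    g <- gradnll(par)
    H <- NULL
  }
  if (is.null(H)) H <- hess(par)

  vcov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vcov) || any(!is.finite(vcov)) || any(diag(vcov) < 0)) {
    warning("observed information is singular or not positive definite; ",
            "covariance unavailable.", call. = FALSE)
    vcov <- matrix(NA_real_, skel$length, skel$length)
  }
  dimnames(vcov) <- list(skel$names, skel$names)
  names(par) <- skel$names

  models <- .unpack(par, skel, causes, coef_names)
  loglik <- -negll(par)
  grad_norm <- sqrt(sum(g^2))
  converged <- converged || grad_norm < 1e-4

  # post-fit validity over the observed design
  if (length(causes) == 2) {
    vc <- validity_check(models$c1, models$c2, aug)
    if (!vc$pass) {
      warning("fitted sub-distribution plateaus sum to ",
              format(vc$total, digits = 4),
              " > 1 at an observed covariate profile (row ", vc$worst_row,
              ").", call. = FALSE)
    }
  }

  structure(list(
    estimates = par, vcov = vcov, loglik = loglik, converged = converged,
    grad_norm = grad_norm, n_used = nrow(aug), n_dropped = n0 - nrow(aug),
    n_events = c(`1` = sum(data$event == 1L), `2` = sum(data$event == 2L)),
    causes = causes, cause_labels = cause_labels, models = models,
    skeleton = skel, coef_names = coef_names,
    designs = lapply(designs, function(d) d[c("xlevels", "terms")]),
    data = aug, control = control
  ), class = "crisk_fit")
}

#' @export
print.crisk_fit <- function(x, ...) {
  cat("Gompertz competing-risks fit\n")
  cat(sprintf("  causes modeled: %s\n",
              paste(x$cause_labels[x$causes], collapse = ", ")))
  cat(sprintf("  n = %d (events: %d / %d), log-likelihood = %.3f\n",
              x$n_used, x$n_events[1], x$n_events[2], x$loglik))
  cat(sprintf("  converged: %s (|grad| = %.2e)\n", x$converged, x$grad_norm))
  for (k in x$causes) {
    ck <- paste0("c", k)
    m <- x$models[[ck]]
    cat(sprintf("  %s: theta = %.4g, gamma = %.4g, rate = %.4g, plateau = %.4g\n",
                x$cause_labels[k], m$params$theta, m$params$gamma,
                m$params$rate, gomp_plateau(m$params)))
    if (length(m$beta)) {
      shr <- exp(m$beta)
      cat(sprintf("    S-HR: %s\n",
                  paste(sprintf("%s = %.3f", names(shr), shr), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
logLik.crisk_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates),
            nobs = object$n_used, class = "logLik")
}
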