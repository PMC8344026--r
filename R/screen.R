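# Univariate -> multivariate prognostic-factor screening for two competing
# events, following the epidemiological convention of a permissive
# univariate p-value gate (default 0.25, reported with 75% intervals)
# followed by a joint model of the retained variables per cause (default
# gate 0.10, reported with 90% intervals), with an explicit collinearity
# pruning step in between.

#' Univariate competing-risks screen
#'
#' Fits, for each candidate variable, a two-cause model in which the
#' variable acts only on the outcome cause's rate (the competing cause is
#' always kept in the likelihood, intercept-only).  A variable is retained
#' when any of its coefficients has a Wald p-value below `threshold`.
#'
#' @param data Cohort data frame (`time`, `event`, covariates).
#' @param variables Character vector of candidate covariate names.
#' @param outcome Which cause the variables act on: 1 or 2.
#' @param threshold Retention p-value gate (default 0.25).
#' @param ci_level Confidence level of the reported intervals (default 0.75).
#' @param cause_labels Labels for causes 1 and 2.
#' @param control Optimizer settings, see [crisk_control()].
#' @return A tibble with one row per coefficient (plus reference-category
#'   rows): `variable`, `level`, `term`, `reference`, `shr`, `conf.low`,
#'   `conf.high`, `p.value`, `retained`, `status`.  A variable whose fit
#'   fails is reported with `status = "failed"` and the screen continues.
#' @export
univariate_screen <- function(data, variables, outcome = 1, threshold = 0.25,
                              ci_level = 0.75,
                              cause_labels = c("death", "transplant"),
                              control = crisk_control(multistart = 2)) {
  stopifnot(outcome %in% 1:2)
  .check_records(data)
  if (!any(data$event == outcome)) {
    stop("no events of the outcome cause in `data`.", call. = FALSE)
  }
  causes <- intersect(1:2, unique(c(outcome, data$event[data$event > 0])))
  rows <- list()
  for (v in variables) {
    f1 <- if (outcome == 1) stats::reformulate(sprintf("`%s`", v)) else ~1
    f2 <- if (outcome == 2) stats::reformulate(sprintf("`%s`", v)) else ~1
    tab <- tryCatch({
      fit <- crisk_fit(data, cause1 = f1, cause2 = f2, causes = causes,
                       cause_labels = cause_labels, control = control)
      if (!fit$converged) stop("fit did not converge")
      shr_table(fit, levels = ci_level)
    }, error = function(e) e)
    if (inherits(tab, "error")) {
      rows[[v]] <- tibble::tibble(
        variable = v, level = NA_character_, term = NA_character_,
        reference = FALSE, shr = NA_real_, conf.low = NA_real_,
        conf.high = NA_real_, p.value = NA_real_, retained = FALSE,
        status = "failed")
      next
    }
    tab <- tab[tab$cause == cause_labels[outcome], , drop = FALSE]
    pct <- format(100 * ci_level)
    p_min <- suppressWarnings(min(tab$p.value, na.rm = TRUE))
    rows[[v]] <- tibble::tibble(
      variable = v, level = tab$level, term = tab$term,
      reference = tab$reference, shr = tab$shr,
      conf.low = tab[[paste0("conf.low.", pct)]],
      conf.high = tab[[paste0("conf.high.", pct)]],
      p.value = tab$p.value,
      retained = is.finite(p_min) && p_min < threshold,
      status = "ok")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "outcome") <- cause_labels[outcome]
  attr(out, "threshold") <- threshold
  attr(out, "ci_level") <- ci_level
  out
}

# association strength on [0, 1] for a mixed-type pair: |Pearson| for two
# numerics, sqrt(R^2) of the one-way fit for numeric~factor, Cramer's V for
# two factors
.pair_assoc <- function(a, b) {
  num_a <- is.numeric(a); num_b <- is.numeric(b)
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (num_a && num_b) return(abs(stats::cor(a, b)))
  if (xor(num_a, num_b)) {
    y <- if (num_a) a else b
    g <- factor(if (num_a) b else a)
    if (nlevels(droplevels(g)) < 2 || stats::var(y) == 0) return(0)
    return(sqrt(summary(stats::lm(y ~ g))$r.squared))
  }
  tab <- table(droplevels(factor(a)), droplevels(factor(b)))
  if (any(dim(tab) < 2)) return(0)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  sqrt(unname(chi) / (sum(tab) * (min(dim(tab)) - 1)))
}

#' Pairwise collinearity check over mixed-type covariates
#'
#' Computes an absolute association measure for every pair of candidate
#' variables (Pearson correlation for numeric pairs, square root of the
#' one-way R² for numeric-categorical pairs, Cramér's V for categorical
#' pairs) and reports pairs exceeding `bound`.  For each offending pair the
#' later-listed member is marked for dropping, so the pruning is
#' deterministic in the input order.
#'
#' @param data Data frame with the variables.
#' @param variables Character vector (>= 2 for a non-trivial check).
#' @param bound Association bound (default 0.8).
#' @return A tibble with `var1`, `var2`, `assoc`, `drop` (the later-listed
#'   member); zero rows when no pair exceeds the bound.
#' @export
collinearity_check <- function(data, variables, bound = 0.8) {
  stopifnot(is.data.frame(data))
  variables <- intersect(variables, names(data))
  if (length(variables) < 2) {
    return(tibble::tibble(var1 = character(0), var2 = character(0),
                          assoc = numeric(0), drop = character(0)))
  }
  pairs <- utils::combn(variables, 2)
  assoc <- apply(pairs, 2, function(p) .pair_assoc(data[[p[1]]], data[[p[2]]]))
  out <- tibble::tibble(var1 = pairs[1, ], var2 = pairs[2, ], assoc = assoc,
                        drop = pairs[2, ])
  out[is.finite(out$assoc) & out$assoc > bound, , drop = FALSE]
}

#' Multivariate competing-risks model of the retained variables
#'
#' Fits one joint model containing, for each cause, that cause's retained
#' covariates, and reports adjusted sub-hazard ratios with intervals at
#' `ci_level` and significance flags at `threshold`.
#'
#' @param data Cohort data frame.
#' @param retained1,retained2 Character vectors of covariates retained for
#'   causes 1 and 2 (either may be empty, but not both).
#' @param threshold Significance gate for flagging (default 0.10).
#' @param ci_level Interval level (default 0.90).
#' @inheritParams univariate_screen
#' @return A list with `fit` (the [crisk_fit()]) and `table` (an
#'   [shr_table()] augmented with a `significant` flag).
#' @export
multivariate_fit <- function(data, retained1, retained2 = character(0),
                             threshold = 0.10, ci_level = 0.90,
                             cause_labels = c("death", "transplant"),
                             control = crisk_control()) {
  if (length(retained1) == 0 && length(retained2) == 0) {
    stop("no retained variables for either cause; nothing to fit.",
         call. = FALSE)
  }
  mkform <- function(vs) {
    if (length(vs) == 0) return(~1)
    stats::reformulate(sprintf("`%s`", vs))
  }
  causes <- intersect(1:2, unique(data$event[data$event > 0]))
  fit <- crisk_fit(data, cause1 = mkform(retained1),
                   cause2 = mkform(retained2), causes = causes,
                   cause_labels = cause_labels, control = control)
  if (length(fit$estimates) == 3 * length(causes)) {
    stop("retained variables yield no estimable contrast ",
         "(reference-only categories?).", call. = FALSE)
  }
  tab <- shr_table(fit, levels = ci_level)
  tab$significant <- !tab$reference & is.finite(tab$p.value) &
    tab$p.value < threshold
  attr(tab, "threshold") <- threshold
  attr(tab, "ci_level") <- ci_level
  list(fit = fit, table = tab)
}

#' Cumulative incidence table from an intercept-only model
#'
#' Fits the intercept-only two-cause model to the cohort and evaluates its
#' cumulative incidence functions at the requested years, in percent —
#' the standard "x-year cumulative incidence" table of a competing-risks
#' analysis.
#'
#' @param data Cohort data frame.
#' @param years Evaluation times (years).
#' @inheritParams univariate_screen
#' @return A tibble with `year` and one percentage column per cause.
#' @export
cumulative_incidence_table <- function(data, years = 1:4,
                                       cause_labels = c("death", "transplant"),
                                       control = crisk_control()) {
  .check_records(data)
  causes <- intersect(1:2, unique(data$event[data$event > 0]))
  fit <- crisk_fit(data, causes = causes, cause_labels = cause_labels,
                   control = control)
  cc <- cif_curve(fit, times = years)
  wide <- tidyr::pivot_wider(cc, names_from = "cause",
                             values_from = "cif")
  for (nm in setdiff(names(wide), "time")) wide[[nm]] <- 100 * wide[[nm]]
  names(wide)[names(wide) == "time"] <- "year"
  wide
}
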