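# MLE fitting, Wald inference, S-HR tables and model-based cumulative
# incidence.

fit_once <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- simulate_recovery(3000, seed = 42)
      cache <<- list(
        cohort = coh,
        fit = suppressWarnings(crisk_fit(coh, cause1 = ~ x, cause2 = ~ x,
                                         control = fast_control())))
    }
    cache
  }
})

test_that("estimates recover the generating parameters within 3 SEs", {
  fx <- fit_once()
  fit <- fx$fit
  expect_true(fit$converged)
  truth <- recovery_truth()$transformed
  se <- sqrt(diag(fit$vcov))
  z <- abs(fit$estimates[names(truth)] - truth) / se[names(truth)]
  expect_true(all(z < 3))
})

test_that("the optimum dominates the truth and scales with duplication", {
  fx <- fit_once()
  fit <- fx$fit
  tr <- recovery_truth()
  cm1 <- cause_model(gomp_params(tr$theta1, tr$gamma1, tr$lambda1),
                     c(x = tr$beta1))
  cm2 <- cause_model(gomp_params(tr$theta2, tr$gamma2, tr$lambda2),
                     c(x = tr$beta2))
  expect_gte(fit$loglik, crisk_loglik(fx$cohort, cm1, cm2))
  # duplicated data: same estimates, doubled loglik, SEs shrink by 1/sqrt(2)
  coh_small <- simulate_recovery(500, seed = 9)
  f1 <- suppressWarnings(crisk_fit(coh_small, cause1 = ~ x, cause2 = ~ x,
                                   control = fast_control()))
  f2 <- suppressWarnings(crisk_fit(dplyr::bind_rows(coh_small, coh_small),
                                   cause1 = ~ x, cause2 = ~ x,
                                   control = fast_control()))
  expect_equal(unname(f2$estimates), unname(f1$estimates), tolerance = 1e-4)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
  expect_equal(sqrt(diag(f2$vcov)), sqrt(diag(f1$vcov)) / sqrt(2),
               tolerance = 1e-3)
})

test_that("the reported optimum is a stationary point of the likelihood", {
  coh <- simulate_recovery(400, seed = 5)
  fit <- suppressWarnings(
    crisk_fit(coh, cause1 = ~ x, cause2 = ~ x, control = fast_control()))
  expect_lt(fit$grad_norm, 1e-4)
  # numerical gradient self-consistency at random parameter points: a
  # coarse central difference matches a tighter one
  negll <- function(par) {
    cms <- gompcr:::.unpack(par, fit$skeleton, fit$causes, fit$coef_names)
    -crisk_loglik(fit$data, cms$c1, cms$c2)
  }
  set.seed(88)
  X <- as.matrix(fit$data[, "x", drop = FALSE])
  for (r in 1:5) {
    p0 <- fit$estimates + rnorm(length(fit$estimates), sd = 0.2)
    g_coarse <- gompcr:::.num_grad(negll, p0, h = 1e-4)
    g_tight <- gompcr:::.num_grad(negll, p0, h = 1e-6)
    expect_equal(g_coarse, g_tight, tolerance = 1e-3)
    # the analytic score used by the optimizer agrees with both
    cms <- gompcr:::.unpack(p0, fit$skeleton, fit$causes, fit$coef_names)
    sb <- gompcr:::.score_blocks(fit$data$time, fit$data$event, X, X,
                                 cms$c1, cms$c2)
    expect_equal(-c(sb$c1, sb$c2), g_tight, tolerance = 1e-6)
  }
})

test_that("fit preconditions and failure modes are explicit", {
  coh <- simulate_recovery(200, seed = 3)
  no2 <- coh[coh$event != 2, ]
  expect_error(crisk_fit(no2, causes = c(1, 2)), "no events of cause 2")
  # single-cause fit works when the other cause is absent
  f <- suppressWarnings(
    crisk_fit(no2, cause1 = ~ x, causes = 1, control = fast_control()))
  expect_true(f$converged)
  expect_length(f$estimates, 4)
  expect_error(crisk_fit(coh, causes = 1), "unmodeled cause")
})

test_that("missing covariates are dropped with a message", {
  coh <- simulate_recovery(300, seed = 12)
  coh$x[c(5, 17)] <- NA
  suppressWarnings(expect_message(
    f <- crisk_fit(coh, cause1 = ~ x, cause2 = ~ x,
                   control = fast_control()),
    "dropped 2"))
  expect_equal(f$n_used, 298)
})

test_that("wald_ci is monotone in level and transform-equivariant", {
  fit <- fit_once()$fit
  ci75 <- wald_ci(fit, level = 0.75)
  ci90 <- wald_ci(fit, level = 0.90)
  expect_true(all(ci90$conf.low < ci75$conf.low))
  expect_true(all(ci90$conf.high > ci75$conf.high))
  expect_equal(ci90$shr.low, exp(ci90$conf.low), tolerance = 1e-12)
  expect_equal(ci90$shr.high, exp(ci90$conf.high), tolerance = 1e-12)
  expect_equal(ci90$shr, exp(ci90$estimate), tolerance = 1e-12)
  expect_error(wald_ci(fit, term = "nonexistent"), "unknown coefficient")
  one <- wald_ci(fit, term = "c1:x", level = 0.9)
  expect_equal(nrow(one), 1)
})

test_that("shr_table reproduces wald_ci and renders reference rows as 1", {
  coh <- simulate_recovery(500, seed = 21)
  coh$grp <- factor(sample(c("low", "mid", "high"), nrow(coh), TRUE),
                    levels = c("low", "mid", "high"))
  fit <- suppressWarnings(crisk_fit(coh, cause1 = ~ x + grp, cause2 = ~ x,
                                    control = fast_control()))
  tab <- shr_table(fit, levels = c(0.75, 0.90))
  expect_true(all(c("conf.low.75", "conf.high.75", "conf.low.90",
                    "conf.high.90", "shr_ci_75", "shr_ci_90") %in% names(tab)))
  ref <- tab[tab$reference & !is.na(tab$shr), ]
  expect_true(all(ref$shr == 1))
  expect_true(all(ref$shr_ci_75 == "1"))
  # round trip against wald_ci
  ci <- wald_ci(fit, level = 0.90)
  merged <- dplyr::inner_join(tab[!tab$reference, ], ci,
                              by = c("cause", "term"))
  expect_equal(merged$conf.low.90, merged$shr.low, tolerance = 1e-12)
  expect_equal(merged$shr.x, merged$shr.y, tolerance = 1e-12)
  expect_equal(merged$p.value.x, merged$p.value.y, tolerance = 1e-12)
})

test_that("null effects give S-HR near 1 with covering intervals", {
  cfg <- recovery_config(800)
  coh <- suppressWarnings(simulate_cohort(cfg, seed = 14))
  coh$noise <- withr::with_seed(15, rnorm(nrow(coh)))
  fit <- suppressWarnings(crisk_fit(coh, cause1 = ~ noise, cause2 = ~ noise,
                                    control = fast_control()))
  ci <- wald_ci(fit, level = 0.95)
  expect_true(all(ci$shr.low < 1 & 1 < ci$shr.high))
  expect_true(all(abs(ci$estimate) < 0.25))
})

test_that("tidy and glance summarize the fit", {
  fit <- fit_once()$fit
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8)
  expect_setequal(unique(td$type), c("baseline", "coefficient"))
  tde <- tidy(fit, exponentiate = TRUE, conf.int = TRUE, conf.level = 0.9)
  cf <- tde$type == "coefficient"
  expect_equal(tde$estimate[cf], exp(td$estimate[cf]), tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$nobs, 3000)
  expect_true(gl$converged)
  expect_equal(gl$logLik, fit$loglik)
  expect_equal(unname(logLik(fit)), fit$loglik, ignore_attr = TRUE)
})

test_that("cif_curve is monotone, bounded, and zero at the origin", {
  fit <- fit_once()$fit
  grid <- seq(0, 8, length.out = 1000)
  cc <- cif_curve(fit, newdata = data.frame(x = 0.3), times = grid)
  wide <- tidyr::pivot_wider(cc, names_from = "cause", values_from = "cif")
  expect_equal(wide$death[1], 0)
  expect_equal(wide$transplant[1], 0)
  expect_true(all(diff(wide$death) >= -1e-12))
  expect_true(all(diff(wide$transplant) >= -1e-12))
  expect_true(all(wide$death + wide$transplant <= 1 + 1e-12))
})

test_that("intercept-only CIF tracks the Aalen-Johansen estimate", {
  skip_if_not_installed("survival")
  coh <- simulate_recovery(2000, seed = 77)
  fit <- crisk_fit(coh, control = fast_control())
  sf <- survival::survfit(
    survival::Surv(time, factor(event, 0:2,
                                c("censor", "death", "transplant"))) ~ 1,
    data = coh)
  keep <- sf$time <= 4
  aj <- sf$pstate[keep, match(c("death", "transplant"), sf$states)]
  cc <- cif_curve(fit, times = sf$time[keep])
  wide <- tidyr::pivot_wider(cc, names_from = "cause", values_from = "cif")
  expect_lt(max(abs(wide$death - aj[, 1])), 0.03)
  expect_lt(max(abs(wide$transplant - aj[, 2])), 0.03)
})
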