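# Synthetic-cohort generator: determinism, covariate distributions,
# sub-distribution fidelity and the packaged default calibration.

test_that("configuration invariants are enforced", {
  expect_error(cov_categorical(c("a", "b"), c(0.6, 0.5)), "sum to 1")
  expect_error(cov_categorical(c("a", "b"), c(1.5, -0.5)), "non-negative")
  expect_error(cov_normal(0, -1), "sd")
  expect_error(recovery_config(0), "n >= 1")
  cfg <- recovery_config(10)
  expect_error(cohort_config(10, cfg$covariates, cfg$truth, study_years = 0),
               "study_years")
  expect_s3_class(default_cohort_config(), "cohort_config")
})

test_that("cohorts are byte-identical under the same seed", {
  cfg <- default_cohort_config(seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(cfg, seed = 124)
  expect_false(identical(a, c2))
  expect_equal(nrow(a), 109)
  expect_true(all(a$time > 0))
  expect_true(all(a$event %in% 0:2))
  # censored + event fractions always sum to 1
  expect_equal(sum(table(factor(a$event, 0:2))) / nrow(a), 1)
})

test_that("a vanishing study window censors everything at ~0", {
  cfg <- recovery_config(200)
  cfg$study_years <- 1e-9
  coh <- suppressWarnings(simulate_cohort(cfg, seed = 2))
  expect_true(all(coh$event == 0))
  expect_true(all(coh$time <= 1e-6 + 1e-12))
})

test_that("with no effects and no truncation the cause mix matches plateaus", {
  tr <- recovery_truth()
  cfg <- cohort_config(
    n = 20000,
    covariates = list(x = cov_normal(0, 1)),
    truth = list(
      formula = ~ x,
      cause1 = cause_model(gomp_params(tr$theta1, tr$gamma1, tr$lambda1),
                           c(x = 0)),
      cause2 = cause_model(gomp_params(tr$theta2, tr$gamma2, tr$lambda2),
                           c(x = 0))),
    study_years = 1e6, seed = 4)
  coh <- simulate_cohort(cfg)
  p1 <- gomp_plateau(gomp_params(tr$theta1, tr$gamma1, tr$lambda1))
  se <- sqrt(p1 * (1 - p1) / nrow(coh))
  expect_lt(abs(mean(coh$event == 1) - p1), 3 * se)
})

test_that("event times follow the conditional sub-distribution", {
  # fixed covariate profile, no censoring: observed cause-k times are
  # draws from F_k(t|x)/plateau_k(x)
  tr <- recovery_truth()
  cm1 <- cause_model(gomp_params(tr$theta1, tr$gamma1, tr$lambda1),
                     c(x = tr$beta1))
  cm2 <- cause_model(gomp_params(tr$theta2, tr$gamma2, tr$lambda2),
                     c(x = tr$beta2))
  cfg <- cohort_config(
    n = 10000,
    covariates = list(x = cov_normal(0.5, 1e-12)),  # essentially degenerate
    truth = list(formula = ~ x, cause1 = cm1, cause2 = cm2),
    study_years = 1e6, seed = 6)
  coh <- simulate_cohort(cfg)
  x0 <- c(x = 0.5)
  t1 <- coh$time[coh$event == 1]
  pl1 <- cause_plateau(matrix(0.5, dimnames = list(NULL, "x")), cm1)
  ks <- suppressWarnings(
    ks.test(t1, function(q) cause_cdf(q, x0, cm1) / pl1))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(length(t1)))
})

test_that("default covariate distributions match the cohort profile", {
  cfg <- default_cohort_config()
  covs <- draw_covariates(cfg, n = 50000, seed = 314)
  expect_lt(abs(mean(covs$age) - 57.99), 0.5)
  expect_gte(min(covs$age), 18)
  male <- mean(covs$gender == "male")
  expect_lt(abs(male - 0.716), 3 * sqrt(0.716 * 0.284 / 50000))
  expect_lt(abs(mean(covs$uric) - 7.00), 0.05)
  phos <- prop.table(table(covs$phos))
  expect_equal(unname(as.vector(phos)),
               c(0.046, 0.193, 0.514, 0.248) / 1.001, tolerance = 0.02)
})

test_that("the default truth reproduces the published 4-year incidences", {
  cfg <- default_cohort_config()
  val <- validate_config(cfg, n = 50000, seed = 27182)
  expect_true(val$pass)
  # deterministic property of the calibrated truth (Monte-Carlo averaging
  # over covariates only): true 4-year CIFs within 1 point of 48.4 / 29.2
  expect_lt(abs(val$mean_cif4[1] - 0.484), 0.01)
  expect_lt(abs(val$mean_cif4[2] - 0.292), 0.01)
})

test_that("replicate default cohorts reproduce the published event mix", {
  cfg <- default_cohort_config()
  mix <- vapply(1:80, function(s) {
    coh <- simulate_cohort(cfg, seed = 5000 + s)
    c(mean(coh$event == 1), mean(coh$event == 2))
  }, numeric(2))
  expect_lt(abs(mean(mix[1, ]) - 0.266), 0.015)
  expect_lt(abs(mean(mix[2, ]) - 0.174), 0.015)
})

test_that("cohort CSV round trip preserves the records", {
  cfg <- default_cohort_config(seed = 88)
  coh <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-12)
  # empty cohort: header-only file reads back empty
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh[0, ], path2)
  expect_equal(nrow(read_cohort(path2)), 0)
})

test_that("malformed cohort files are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,event,x",
               "1.0,1,0.2", "2.0,0,0.1", "0.5,2,0.0", "1.1,1,0.4",
               "2.2,0,0.3", "0.9,2,0.2", "1.5,3,0.1"), path)
  expect_error(read_cohort(path), "line\\(s\\): 8")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,event,x", "1.0,1,0.2", "-2.0,0,0.1"), path2)
  expect_error(read_cohort(path2), "line\\(s\\): 3")
})

test_that("configurations survive the YAML round trip", {
  cfg <- default_cohort_config(seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$n, cfg$n)
  expect_equal(cfg2$truth$cause1$params$gamma, cfg$truth$cause1$params$gamma,
               tolerance = 1e-12)
  expect_equal(cfg2$truth$cause2$beta, cfg$truth$cause2$beta,
               tolerance = 1e-12)
  # YAML carries 15 significant digits, so cohorts agree to float formatting
  a <- simulate_cohort(cfg2, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a$event, b$event)
  expect_equal(a$time, b$time, tolerance = 1e-10)
  expect_identical(a[, -(1:2)], b[, -(1:2)])
})
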