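# Clinical categorization and the univariate -> multivariate screening
# pipeline.

test_that("categorize bins labs exactly as printed", {
  rules <- default_category_rules()
  df <- data.frame(phosphorus = c(5.0, 4.7, 4.6, 9.9),
                   pth = c(700, 150, 600, 30),
                   hemoglobin = c(10, 9.9, 12.5, 12.6),
                   potassium = c(3.5, 5, 5.1, 4),
                   alp = c(299, 301, 250, 10),
                   hba1c = c(6.9, 7.1, 5, 8),
                   calcium = c(8.5, 8.4, 9.5, 9.6),
                   albumin = c(4, 3.9, 6.3, 5))
  out <- categorize(df, rules)
  expect_equal(as.character(out$phosphorus_cat),
               c("4.7-5.7", "4.7-5.7", "2.7-4.6", "6.9-9.9"))
  expect_equal(as.character(out$pth_cat), c(">600", "150-600", "150-600", "<150"))
  expect_equal(as.character(out$hemoglobin_cat),
               c("10-12.5", "<10", "10-12.5", ">12.5"))
  expect_equal(as.character(out$potassium_cat), c("3.5-5", "3.5-5", ">5", "3.5-5"))
  # reference category comes first in the factor levels
  expect_equal(levels(out$phosphorus_cat)[1], "2.7-4.6")
  expect_equal(levels(out$hemoglobin_cat)[1], "10-12.5")
})

test_that("out-of-range values are labeled explicitly, not clamped", {
  rules <- default_category_rules()
  df <- data.frame(phosphorus = c(5.0, 1.0, 10.5))
  expect_warning(out <- categorize(df, rules[rules$variable == "phosphorus", ]),
                 "out-of-range")
  expect_equal(as.character(out$phosphorus_cat),
               c("4.7-5.7", "out-of-range", "out-of-range"))
  expect_error(categorize(data.frame(other = 1), rules), "not found")
})

test_that("a strong true effect is retained by the univariate screen", {
  cfg <- recovery_config(1000)
  # strengthen the cause-1 effect to the screening-oracle level
  cfg$truth$cause1$beta <- c(x = 0.7)
  coh <- suppressWarnings(simulate_cohort(cfg, seed = 60))
  coh$noise <- withr::with_seed(61, rnorm(nrow(coh)))
  scr <- suppressWarnings(univariate_screen(coh, c("x", "noise"), outcome = 1))
  expect_true(all(scr$retained[scr$variable == "x"]))
  expect_equal(sort(unique(scr$variable)), c("noise", "x"))
  expect_true(all(scr$status == "ok"))
  # empty variable list gives an empty report
  expect_equal(nrow(univariate_screen(coh, character(0), outcome = 1)), 0)
})

test_that("screen reports every variable exactly once per outcome", {
  cfg <- default_cohort_config()
  coh <- simulate_cohort(cfg, seed = 70)
  vars <- c("age", "uric", "phos")
  scr <- suppressWarnings(
    univariate_screen(coh, vars, outcome = 1,
                      control = crisk_control(multistart = 1)))
  # one block of rows per variable; factor variables additionally carry a
  # reference row
  expect_setequal(unique(scr$variable), vars)
  counts <- table(scr$variable[!scr$reference | is.na(scr$term)])
  expect_equal(unname(counts[["age"]]), 1)
  expect_equal(unname(counts[["phos"]]), 4)  # 3 contrasts + reference
})

test_that("collinearity check flags duplicates and spares independence", {
  set.seed(90)
  df <- data.frame(a = rnorm(1000), b = rnorm(1000),
                   g = factor(sample(c("u", "v"), 1000, TRUE)))
  df$dup <- df$a
  out <- collinearity_check(df, c("a", "b", "g", "dup"))
  expect_equal(nrow(out), 1)
  expect_equal(out$var1, "a")
  expect_equal(out$drop, "dup")
  expect_equal(out$assoc, 1, tolerance = 1e-12)
  # independent covariates: nothing above the bound
  expect_equal(nrow(collinearity_check(df, c("a", "b", "g"))), 0)
  # single variable or fewer: empty result
  expect_equal(nrow(collinearity_check(df, "a")), 0)
  # mixed-type association: numeric vs its own three-level binning is strong
  df$a_cat <- cut(df$a, c(-Inf, -0.43, 0.43, Inf))
  out2 <- collinearity_check(df, c("a", "a_cat"))
  expect_equal(nrow(out2), 1)
})

test_that("multivariate fit flags monotonically in the threshold", {
  cfg <- default_cohort_config()
  coh <- simulate_cohort(cfg, seed = 75)
  mv10 <- suppressWarnings(
    multivariate_fit(coh, retained1 = c("age", "uric"),
                     retained2 = c("age", "uric"), threshold = 0.10,
                     control = crisk_control(multistart = 1)))
  mv05 <- suppressWarnings(
    multivariate_fit(coh, retained1 = c("age", "uric"),
                     retained2 = c("age", "uric"), threshold = 0.05,
                     control = crisk_control(multistart = 1)))
  sig10 <- mv10$table$significant
  sig05 <- mv05$table$significant
  expect_true(all(which(sig05) %in% which(sig10)))
  expect_error(multivariate_fit(coh, character(0), character(0)),
               "no retained variables")
})

test_that("cumulative incidence table is monotone and zero at year 0", {
  coh <- simulate_recovery(1500, seed = 80)
  tab <- cumulative_incidence_table(coh, years = 1:4,
                                    control = crisk_control(multistart = 1))
  expect_equal(names(tab), c("year", "death", "transplant"))
  expect_true(all(diff(tab$death) >= 0))
  expect_true(all(diff(tab$transplant) >= 0))
  expect_true(all(tab$death + tab$transplant <= 100))
  tab0 <- cumulative_incidence_table(coh, years = 0,
                                     control = crisk_control(multistart = 1))
  expect_equal(unname(unlist(tab0[1, c("death", "transplant")])), c(0, 0))
})

test_that("incidence table tracks the generating truth on a large cohort", {
  cfg <- recovery_config(5000)
  coh <- suppressWarnings(simulate_cohort(cfg, seed = 85))
  tab <- cumulative_incidence_table(coh, years = 1:4,
                                    control = crisk_control(multistart = 1))
  tr <- recovery_truth()
  cm1 <- cause_model(gomp_params(tr$theta1, tr$gamma1, tr$lambda1),
                     c(x = tr$beta1))
  cm2 <- cause_model(gomp_params(tr$theta2, tr$gamma2, tr$lambda2),
                     c(x = tr$beta2))
  # covariate sample matching the generator's truncated support
  X <- withr::with_seed(
    86, data.frame(x = qnorm(runif(40000, pnorm(-2.7), pnorm(2.7)))))
  for (y in 1:4) {
    truth1 <- 100 * mean(cause_cdf(y, X, cm1))
    truth2 <- 100 * mean(cause_cdf(y, X, cm2))
    expect_lt(abs(tab$death[tab$year == y] - truth1), 2)
    expect_lt(abs(tab$transplant[tab$year == y] - truth2), 2)
  }
})

test_that("the full pipeline runs end to end, deterministically", {
  cfg <- default_cohort_config()
  coh <- simulate_cohort(cfg, seed = 99)
  out_dir <- withr::local_tempdir()
  suppressWarnings(suppressMessages(
    rep1 <- run_screening(coh, variables = c("age", "uric", "phos", "gender"),
                          out_dir = out_dir,
                          control = crisk_control(multistart = 1))))
  expect_s3_class(rep1, "screen_report")
  expect_named(rep1$univariate, c("death", "transplant"))
  expect_true(all(c("year", "death", "transplant") %in% names(rep1$incidence)))
  expect_true(file.exists(file.path(out_dir, "report.md")))
  expect_true(file.exists(file.path(out_dir, "univariate_death.tsv")))
  expect_true(file.exists(file.path(out_dir, "cumulative_incidence.tsv")))
  expect_true(file.exists(file.path(out_dir, "run.log")))
  # identical input and settings give identical reports
  suppressWarnings(suppressMessages(
    rep2 <- run_screening(coh, variables = c("age", "uric", "phos", "gender"),
                          control = crisk_control(multistart = 1))))
  expect_equal(rep1$univariate, rep2$univariate)
  expect_equal(rep1$incidence, rep2$incidence)
})

test_that("a cohort with no transplants omits cause-2 tables with a note", {
  cfg <- recovery_config(400)
  coh <- suppressWarnings(simulate_cohort(cfg, seed = 103))
  coh <- coh[coh$event != 2, ]
  suppressMessages(
    rep <- run_screening(coh, variables = "x",
                         cause_labels = c("death", "transplant"),
                         control = crisk_control(multistart = 1)))
  expect_false("transplant" %in% names(rep$univariate))
  expect_true(any(grepl("transplant", rep$notes)))
  expect_true("death" %in% names(rep$univariate))
})

test_that("lowering the univariate threshold never adds retained variables", {
  cfg <- default_cohort_config()
  coh <- simulate_cohort(cfg, seed = 110)
  vars <- c("age", "uric", "gender")
  s25 <- univariate_screen(coh, vars, outcome = 1, threshold = 0.25,
                           control = crisk_control(multistart = 1))
  s05 <- univariate_screen(coh, vars, outcome = 1, threshold = 0.05,
                           control = crisk_control(multistart = 1))
  kept25 <- unique(s25$variable[s25$retained])
  kept05 <- unique(s05$variable[s05$retained])
  expect_true(all(kept05 %in% kept25))
})
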