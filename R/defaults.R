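# Packaged default cohort: a synthetic end-stage renal disease cohort of
# hemodialysis patients followed over a 4-year enrolment window, with death
# on dialysis (cause 1) competing against kidney transplantation (cause 2).
#
# Covariate distributions mirror the published cohort profile this package
# is calibrated against: n = 109, 71.6% male, age 57.99 +/- 17.10 years
# (truncated to adults), serum uric acid 7.00 +/- 1.33 mg/dl, and a
# four-level serum phosphorus category.  The remaining laboratory variables
# are generated with no effect on either cause, as noise covariates for
# screening studies.
#
# The true cause models (theta, gamma, rate and the covariate effects) were
# frozen from tools/calibrate-defaults.R, which chooses them so that
#   * the population-averaged true cumulative incidence at 4 years is
#     48.4% (death) and 29.2% (transplant), and
#   * the expected observed event mix under uniform administrative
#     censoring over the 4-year window is 26.6% death / 17.4% transplant,
# with covariate effect signs matching the published prognosis directions
# (older age and higher phosphorus worsen death; younger age, male sex and
# higher uric acid favour transplant).

# frozen output of tools/calibrate-defaults.R -- do not edit by hand
.DEFAULT_TRUTH <- list(
  age_mean = 57.8651,  # underlying normal location; truncation to [18, 100]
                       # brings the realized mean age to 57.99
  cause1 = list(theta = 30.1118, gamma = -0.937363, lrate0 = 1.27756),
  cause2 = list(theta = 3.98082, gamma = -0.770573, lrate0 = 0.0263017),
  beta1 = c(age = 0.00495066, gendermale = 0.115934, uric = -0.0589306,
            `phos4.7-5.7` = 0.099694, `phos5.8-6.8` = 0.0145672,
            `phos6.9-9.9` = -0.127706),
  beta2 = c(age = -0.0102055, gendermale = 0.0946091, uric = 0.135581,
            `phos4.7-5.7` = -0.0406297, `phos5.8-6.8` = 0.0517535,
            `phos6.9-9.9` = 0.349679),
  # mean of x'beta over the covariate mix; lrate0 is the rate at that mean,
  # so rate = exp(lrate0 - mean_eta) at x = 0
  mean_eta1 = -0.0470156,
  mean_eta2 = 0.527359
)

#' Packaged default synthetic dialysis cohort configuration
#'
#' A [cohort_config()] emulating a hemodialysis registry cohort of 109
#' adults enrolled over a 4-year window, with death on dialysis and kidney
#' transplantation as competing events.  Covariate distributions follow the
#' published cohort profile (71.6% male; age 57.99 ± 17.10 years, adults
#' only; uric acid 7.00 ± 1.33 mg/dl; phosphorus categories with
#' frequencies 4.6/19.3/51.4/24.8%), and the true cause models are
#' calibrated so the configuration reproduces the published event mix
#' (26.6% observed deaths, 17.4% observed transplants) and 4-year
#' cumulative incidences (48.4% death, 29.2% transplant).  Eleven further
#' laboratory variables are generated as noise covariates with no effect on
#' either cause.
#'
#' @param n Cohort size (default 109).
#' @param seed Default seed carried by the configuration (optional).
#' @return A [cohort_config()].
#' @examples
#' cfg <- default_cohort_config(seed = 1)
#' cohort <- simulate_cohort(cfg)
#' table(cohort$event)
#' @export
default_cohort_config <- function(n = 109, seed = NULL) {
  tr <- .DEFAULT_TRUTH
  covariates <- list(
    age = cov_normal(tr$age_mean, 17.10, lower = 18, upper = 100),
    gender = cov_categorical(c("female", "male"), c(0.284, 0.716)),
    uric = cov_normal(7.00, 1.33, lower = 3, upper = 11),
    phos = cov_categorical(c("2.7-4.6", "4.7-5.7", "5.8-6.8", "6.9-9.9"),
                           c(0.046, 0.193, 0.514, 0.248) / 1.001),
    ferritin = cov_normal(347.90, 325.43, lower = 5, upper = 2000),
    creatinine = cov_normal(8.93, 3.61, lower = 1, upper = 25),
    cholesterol = cov_normal(146.64, 36.47, lower = 50, upper = 400),
    sgot = cov_normal(18.40, 7.53, lower = 3, upper = 80),
    sgpt = cov_normal(21.33, 13.97, lower = 3, upper = 150),
    bilirubin = cov_normal(0.68, 0.10, lower = 0.2, upper = 1.5),
    hemoglobin = cov_categorical(c("10-12.5", "<10", ">12.5"),
                                 c(0.431, 0.339, 0.229) / 0.999),
    potassium = cov_categorical(c("3.5-5", ">5"), c(0.33, 0.67)),
    alp = cov_categorical(c("<300", ">300"), c(0.541, 0.459)),
    hba1c = cov_categorical(c("<7", ">7"), c(0.881, 0.119)),
    calcium = cov_categorical(c("8.5-9.5", "<8.5", ">9.5"),
                              c(0.734, 0.138, 0.128)),
    pth = cov_categorical(c("150-600", "<150", ">600"),
                          c(0.771, 0.128, 0.101)),
    albumin = cov_categorical(c("<4", "4-6.3"), c(0.22, 0.78))
  )
  mk <- function(b, beta, mean_eta) {
    cause_model(gomp_params(b$theta, b$gamma, exp(b$lrate0 - mean_eta)), beta)
  }
  truth <- list(
    formula = ~ age + gender + uric + phos,
    cause1 = mk(tr$cause1, tr$beta1, tr$mean_eta1),
    cause2 = mk(tr$cause2, tr$beta2, tr$mean_eta2)
  )
  cohort_config(n = n, covariates = covariates, truth = truth,
                study_years = 4, seed = seed)
}
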