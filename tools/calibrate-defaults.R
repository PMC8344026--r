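#!/usr/bin/env Rscript
# Calibrates the packaged default cohort configuration.
#
# Chooses the baseline Gompertz parameters of both causes (and the age
# distribution's location) so that, under the default covariate mix and
# uniform administrative censoring over the 4-year window, the
# configuration reproduces the published cohort summaries:
#   * population-averaged true CIF at 4 years: 48.4% (death), 29.2% (transplant)
#   * expected observed event mix:             26.6% (death), 17.4% (transplant)
#   * mean age 57.99 after truncation to [18, 100]
# Covariate effects are the published adjusted log sub-hazard ratios
# scaled by a single shrink factor (signs preserved); the factor is chosen
# as the largest value in a fixed grid for which the four targets are
# attainable while the two plateaus sum below 1 over the whole (truncated)
# covariate support -- at the published magnitudes the transplant plateau
# saturates at extreme profiles and no valid joint truth exists.
# Intermediate-year incidences enter only as weak shape regularizers.
#
# Output: the frozen constant block pasted into R/defaults.R.

library(gompcr)

## --- age location: truncated-normal mean must equal 57.99 ----------------
age_sd <- 17.10
trunc_mean <- function(m) {
  a <- (18 - m) / age_sd; b <- (100 - m) / age_sd
  m + age_sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
age_mean <- uniroot(function(m) trunc_mean(m) - 57.99, c(40, 70), tol = 1e-10)$root
cat(sprintf("age location: %.6f (truncated mean %.6f)\n",
            age_mean, trunc_mean(age_mean)))

## --- covariate effects: scaled published adjusted log S-HRs ---------------
beta1_full <- c(age = log(1.02), gendermale = log(1.59), uric = log(0.79),
                `phos4.7-5.7` = log(1.49), `phos5.8-6.8` = log(1.06),
                `phos6.9-9.9` = log(0.60))
beta2_full <- c(age = log(0.96), gendermale = log(1.46), uric = log(1.72),
                `phos4.7-5.7` = log(0.85), `phos5.8-6.8` = log(1.23),
                `phos6.9-9.9` = log(4.05))
shrink_grid <- c(0.5, 0.4, 0.35, 0.3, 0.25, 0.2, 0.15)

## --- covariate sample for population averages -----------------------------
set.seed(890123)
n_mc <- 20000
qtrunc <- function(u, m, s, lo, hi)
  qnorm(pnorm(lo, m, s) + u * (pnorm(hi, m, s) - pnorm(lo, m, s)), m, s)
covs <- data.frame(
  age = qtrunc(runif(n_mc), age_mean, age_sd, 18, 100),
  gender = factor(sample(c("female", "male"), n_mc, TRUE, c(0.284, 0.716)),
                  levels = c("female", "male")),
  uric = qtrunc(runif(n_mc), 7.00, 1.33, 3, 11),
  phos = factor(sample(c("2.7-4.6", "4.7-5.7", "5.8-6.8", "6.9-9.9"), n_mc,
                       TRUE, c(0.046, 0.193, 0.514, 0.248) / 1.001),
                levels = c("2.7-4.6", "4.7-5.7", "5.8-6.8", "6.9-9.9")))
X <- model.matrix(~ age + gender + uric + phos, covs)[, -1]

## support grid for the joint-validity constraint (worst-case plateau sum)
grid <- expand.grid(age = seq(18, 100, by = 1), uric = seq(3, 11, by = 0.25),
                    gender = c("female", "male"),
                    phos = c("2.7-4.6", "4.7-5.7", "5.8-6.8", "6.9-9.9"))
grid$gender <- factor(grid$gender, levels = c("female", "male"))
grid$phos <- factor(grid$phos,
                    levels = c("2.7-4.6", "4.7-5.7", "5.8-6.8", "6.9-9.9"))
Xg <- model.matrix(~ age + gender + uric + phos, grid)[, -1]

## --- model pieces ----------------------------------------------------------
# centered parameterization: lrate0 is log-rate at the mean linear predictor
Fbar <- function(t, th, ga, lr0, eta, meta) {
  rate <- exp(lr0 + eta - meta)
  G <- if (abs(ga) < 1e-8) rate * t else (rate / ga) * expm1(ga * t)
  mean((-expm1(-G))^th)
}
plat <- function(th, ga, lr0, eta, meta) {
  if (ga >= 0) return(rep(1, length(eta)))
  rate <- exp(lr0 + eta - meta)
  (-expm1(rate / ga))^th
}

# Gauss-Legendre nodes on (0, 4) for E[F(C)], C ~ U(0, 4)
gl <- gompcr:::.gauss_legendre(12, 0, 4)

targets_hard <- c(F1_4 = 0.484, F2_4 = 0.292, obs1 = 0.266, obs2 = 0.174)
targets_soft <- list(y = 1:3, F1 = c(0.025, 0.142, 0.326),
                     F2 = c(0.0134, 0.226, 0.286))

calibrate_at <- function(shrink) {
  beta1 <- shrink * beta1_full
  beta2 <- shrink * beta2_full
  eta1 <- drop(X %*% beta1); eta2 <- drop(X %*% beta2)
  mean_eta1 <- mean(eta1);   mean_eta2 <- mean(eta2)
  eta1g <- drop(Xg %*% beta1); eta2g <- drop(Xg %*% beta2)

  objective <- function(p) {
  th1 <- exp(p[1]); ga1 <- p[2]; lr1 <- p[3]
  th2 <- exp(p[4]); ga2 <- p[5]; lr2 <- p[6]
  F1_4 <- Fbar(4, th1, ga1, lr1, eta1, mean_eta1)
  F2_4 <- Fbar(4, th2, ga2, lr2, eta2, mean_eta2)
  obs1 <- sum(gl$weights * vapply(gl$nodes, Fbar, 0, th = th1, ga = ga1,
                                  lr0 = lr1, eta = eta1, meta = mean_eta1)) / 4
  obs2 <- sum(gl$weights * vapply(gl$nodes, Fbar, 0, th = th2, ga = ga2,
                                  lr0 = lr2, eta = eta2, meta = mean_eta2)) / 4
  hard <- sum((c(F1_4, F2_4, obs1, obs2) - targets_hard)^2)
  soft <- sum((vapply(targets_soft$y, Fbar, 0, th = th1, ga = ga1, lr0 = lr1,
                      eta = eta1, meta = mean_eta1) - targets_soft$F1)^2) +
          sum((vapply(targets_soft$y, Fbar, 0, th = th2, ga = ga2, lr0 = lr2,
                      eta = eta2, meta = mean_eta2) - targets_soft$F2)^2)
  worst <- max(plat(th1, ga1, lr1, eta1g, mean_eta1) +
               plat(th2, ga2, lr2, eta2g, mean_eta2))
    1e4 * hard + 0.5 * soft + 1e6 * max(0, worst - 0.995)^2
  }

  # the death cause needs a pronounced S-shape (large power) to be both
  # rare in year 1 and at 48.4% by year 4, as the printed incidence table
  # shows; theta is left free
  starts <- list(c(0, -0.3, log(0.17), 0.7, -1.2, log(0.12)),
                 c(0.2, -0.5, log(0.2), 0.3, -0.8, log(0.1)),
                 c(0, -0.2, log(0.15), 0, -1.5, log(0.15)),
                 c(0.5, -0.6, log(0.25), 1.0, -1.0, log(0.12)))
  fits <- lapply(starts, function(s)
    nlminb(s, objective, control = list(iter.max = 2000, eval.max = 4000)))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "objective"))]]
  p <- best$par
  th1 <- exp(p[1]); ga1 <- p[2]; lr1 <- p[3]
  th2 <- exp(p[4]); ga2 <- p[5]; lr2 <- p[6]
  achieved <- c(
    F1_4 = Fbar(4, th1, ga1, lr1, eta1, mean_eta1),
    F2_4 = Fbar(4, th2, ga2, lr2, eta2, mean_eta2),
    obs1 = sum(gl$weights * vapply(gl$nodes, Fbar, 0, th = th1, ga = ga1,
                                   lr0 = lr1, eta = eta1, meta = mean_eta1)) / 4,
    obs2 = sum(gl$weights * vapply(gl$nodes, Fbar, 0, th = th2, ga = ga2,
                                   lr0 = lr2, eta = eta2, meta = mean_eta2)) / 4)
  worst <- max(plat(th1, ga1, lr1, eta1g, mean_eta1) +
               plat(th2, ga2, lr2, eta2g, mean_eta2))
  list(p = p, objective = best$objective, achieved = achieved, worst = worst,
       beta1 = beta1, beta2 = beta2, mean_eta1 = mean_eta1,
       mean_eta2 = mean_eta2, eta1 = eta1, eta2 = eta2)
}

## largest shrink factor whose solution hits every hard target within
## 0.004 while the worst-case plateau sum stays at or below 1 (the
## penalty inside the objective already enforces a 0.995 margin)
sol <- NULL
for (sh in shrink_grid) {
  cand <- calibrate_at(sh)
  resid <- max(abs(cand$achieved - targets_hard))
  cat(sprintf("shrink %.2f: max residual %.4f, worst plateau sum %.4f\n",
              sh, resid, cand$worst))
  if (resid < 0.004 && cand$worst <= 1) { sol <- cand; shrink <- sh; break }
}
stopifnot(!is.null(sol))
cat(sprintf("selected shrink factor: %.2f\n", shrink))

p <- sol$p
beta1 <- sol$beta1; beta2 <- sol$beta2
mean_eta1 <- sol$mean_eta1; mean_eta2 <- sol$mean_eta2
eta1 <- sol$eta1; eta2 <- sol$eta2
th1 <- exp(p[1]); ga1 <- p[2]; lr1 <- p[3]
th2 <- exp(p[4]); ga2 <- p[5]; lr2 <- p[6]
print(rbind(target = targets_hard, achieved = sol$achieved))
cat("year-by-year death:   ",
    vapply(1:4, Fbar, 0, th = th1, ga = ga1, lr0 = lr1, eta = eta1,
           meta = mean_eta1), "\n")
cat("year-by-year transplant:",
    vapply(1:4, Fbar, 0, th = th2, ga = ga2, lr0 = lr2, eta = eta2,
           meta = mean_eta2), "\n")
cat("worst-case plateau sum over support:", sol$worst, "\n")
cat("baseline plateaus:",
    plat(th1, ga1, lr1, mean_eta1, mean_eta1),
    plat(th2, ga2, lr2, mean_eta2, mean_eta2), "\n")

## --- frozen block ----------------------------------------------------------
fmt <- function(x) formatC(x, digits = 6, format = "g")
cat(sprintf('
.DEFAULT_TRUTH <- list(
  age_mean = %s,
  cause1 = list(theta = %s, gamma = %s, lrate0 = %s),
  cause2 = list(theta = %s, gamma = %s, lrate0 = %s),
  beta1 = c(age = %s, gendermale = %s, uric = %s,
            `phos4.7-5.7` = %s, `phos5.8-6.8` = %s,
            `phos6.9-9.9` = %s),
  beta2 = c(age = %s, gendermale = %s, uric = %s,
            `phos4.7-5.7` = %s, `phos5.8-6.8` = %s,
            `phos6.9-9.9` = %s),
  mean_eta1 = %s,
  mean_eta2 = %s
)
', fmt(age_mean), fmt(th1), fmt(ga1), fmt(lr1), fmt(th2), fmt(ga2), fmt(lr2),
   fmt(beta1[1]), fmt(beta1[2]), fmt(beta1[3]), fmt(beta1[4]), fmt(beta1[5]),
   fmt(beta1[6]),
   fmt(beta2[1]), fmt(beta2[2]), fmt(beta2[3]), fmt(beta2[4]), fmt(beta2[5]),
   fmt(beta2[6]), fmt(mean_eta1), fmt(mean_eta2)))
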