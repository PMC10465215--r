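test_that("Newton-Raphson matches the brute-force Breslow oracle on 6-observation toys", {
  surv <- toy_surv_separated()
  # non-separated toy: events alternate over the covariate
  x_alt <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_fit(matrix(x_alt, ncol = 1), surv)
  grid <- optimize(function(b) breslow_loglik_toy(b, x_alt),
                   c(-20, 20), maximum = TRUE, tol = 1e-10)$maximum
  expect_lt(abs(fit$beta - grid), 1e-6)
  expect_true(fit$converged)

  # the monotone-likelihood toy (0,0,0,1,1,1): both the capped fit and the
  # grid maximizer over the documented [-20, 20] domain sit at the boundary
  x_sep <- c(0, 0, 0, 1, 1, 1)
  fit_sep <- cox_fit(matrix(x_sep, ncol = 1), surv)
  grid_sep <- optimize(function(b) breslow_loglik_toy(b, x_sep),
                       c(-20, 20), maximum = TRUE, tol = 1e-10)$maximum
  expect_lt(abs(fit_sep$beta - grid_sep), 1e-4)
  expect_false(fit_sep$converged)  # flagged as monotone likelihood
})

test_that("both tie conventions agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(2)
  tt <- sample(1:6, 60, replace = TRUE)
  ev <- rbinom(60, 1, 0.7)
  x <- cbind(a = rnorm(60), b = rbinom(60, 1, 0.4))
  surv <- survival_table(data.frame(sample = paste0("p", 1:60), time = tt,
                                    event = ev))
  for (m in c("breslow", "efron")) {
    mine <- cox_fit(x, surv, ties = m)
    ref <- survival::coxph(survival::Surv(tt, ev) ~ x, ties = m)
    expect_equal(unname(mine$beta), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
  }
})

test_that("cox_fit is time-scale invariant and covariate-scale equivariant", {
  set.seed(4)
  n <- 150
  x <- rnorm(n)
  tt <- rexp(n, exp(0.5 * x))
  surv <- survival_table(data.frame(sample = 1:n, time = tt, event = 1L))
  f1 <- cox_fit(matrix(x, ncol = 1), surv)
  surv2 <- survival_table(data.frame(sample = 1:n, time = 7.3 * tt,
                                     event = 1L))
  f2 <- cox_fit(matrix(x, ncol = 1), surv2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  f3 <- cox_fit(matrix(2 * x, ncol = 1), surv)
  expect_equal(unname(f3$beta), unname(f1$beta) / 2, tolerance = 1e-6)
})

test_that("null covariates give calibrated Wald p values and HR 2 is recovered", {
  set.seed(31)
  pvals <- vapply(1:50, function(s) {
    n <- 1000
    sv <- survival_table(data.frame(sample = 1:n, time = rexp(n),
                                    event = rbinom(n, 1, 0.7)))
    cox_fit(matrix(rnorm(n), ncol = 1), sv)$p
  }, 0)
  frac <- mean(pvals < 0.05)
  half <- 2.576 * sqrt(0.05 * 0.95 / 50)
  expect_gte(frac, max(0, 0.05 - half))
  expect_lte(frac, 0.05 + half)

  # two-group exponential data with true HR 2, n = 2000, no censoring
  set.seed(32)
  grp <- rep(c(0, 1), each = 1000)
  tt <- rexp(2000, rate = exp(log(2) * grp))
  sv <- survival_table(data.frame(sample = 1:2000, time = tt, event = 1L))
  fit <- cox_fit(matrix(grp, ncol = 1), sv)
  expect_gte(fit$hr, 1.8)
  expect_lte(fit$hr, 2.2)
  # oracle: grid maximization of the Breslow partial likelihood
  o <- order(tt)
  xo <- grp[o]
  grid_ll <- function(b) {
    eta <- xo * b
    sum(eta) - sum(log(rev(cumsum(rev(exp(eta))))))
  }
  grid <- optimize(grid_ll, c(-3, 3), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(unname(fit$beta), grid, tolerance = 1e-4)
})

test_that("error contracts: constant covariate, no events", {
  sv <- survival_table(data.frame(sample = 1:10, time = 1:10, event = 1L))
  expect_error(cox_fit(matrix(1, 10, 1), sv), "no variation")
  sv0 <- survival_table(data.frame(sample = 1:10, time = 1:10, event = 0L))
  expect_error(cox_fit(matrix(rnorm(10), ncol = 1), sv0), "at least one event")
})

test_that("prognostic screen classifies planted genes and controls the null", {
  coh <- fixture("screen_cohort", function()
    generate_cohort(cohort_config(n_samples = 500, seed = 13)))
  sub <- c(coh$truth$protective_genes[1:5], coh$truth$risk_genes[1:5])
  scr <- screen_prognostic(coh$expression$values[sub, ], coh$survival)
  expect_true(all(scr$class[1:5] == "A"))
  expect_true(all(scr$class[6:10] == "B"))
  expect_true(all(scr$hr == exp(scr$beta)))
  # alpha = 0 sends everything to none
  scr0 <- screen_prognostic(coh$expression$values[sub, ], coh$survival,
                            alpha = 0)
  expect_true(all(scr0$class == "none"))
  # null genes misclassified at about the alpha level
  set.seed(14)
  null_expr <- matrix(rnorm(2000 * 300), 2000, 300,
                      dimnames = list(paste0("n", 1:2000), NULL))
  sv <- survival_table(data.frame(sample = 1:300, time = rexp(300),
                                  event = rbinom(300, 1, 0.7)))
  scr_null <- screen_prognostic(null_expr, sv)
  frac <- mean(scr_null$class != "none")
  half <- 2.576 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(frac, 0.05 - half)
  expect_lt(frac, 0.05 + half)
})

test_that("KM without censoring equals the empirical survival function", {
  sv <- survival_table(data.frame(sample = 1:8, time = c(3, 1, 4, 2, 7, 5, 6, 8),
                                  event = 1L))
  km <- km_estimate(sv)
  expect_equal(km$all$survival, 1 - seq_len(8) / 8)
  expect_true(all(diff(km$all$survival) <= 0))
  # last-event identity: S = prod(1 - d_i / n_i)
  expect_equal(km$all$survival[8],
               prod(1 - km$all$n_event / km$all$n_risk))
})

test_that("log-rank matches the hand-worked hypergeometric computation", {
  # A: deaths at 1,2,3; B: deaths at 4,5,6. Hand tables give
  # O_A = 3, E_A = 3/6 + 2/5 + 1/4 = 1.15, V = 0.25 + 0.24 + 0.1875 = 0.6775
  sv <- survival_table(data.frame(sample = 1:6, time = 1:6, event = 1L))
  grp <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(sv, grp)
  expect_equal(unname(lr$observed["A"]), 3)
  expect_equal(unname(lr$expected["A"]), 1.15, tolerance = 1e-12)
  expect_equal(lr$chisq, (3 - 1.15)^2 / 0.6775, tolerance = 1e-6)
  expect_identical(lr$df, 1L)
  skip_if_not_installed("survival")
  ref <- survival::survdiff(survival::Surv(1:6, rep(1, 6)) ~ grp)
  expect_equal(lr$chisq, ref$chisq, tolerance = 1e-8)
})

test_that("identical survival duplicated into two groups gives a null log-rank", {
  sv <- survival_table(data.frame(sample = 1:12,
                                  time = rep(c(2, 4, 5, 7, 8, 9), 2),
                                  event = rep(c(1L, 0L, 1L, 1L, 0L, 1L), 2)))
  lr <- logrank_test(sv, rep(c("x", "y"), each = 6))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
})

test_that("two-group log-rank p agrees with the Cox score-type p at large n", {
  set.seed(9)
  n <- 1000
  grp <- rep(0:1, each = n / 2)
  tt <- rexp(n, exp(0.15 * grp))
  sv <- survival_table(data.frame(sample = 1:n, time = tt, event = 1L))
  lr <- logrank_test(sv, grp)
  cf <- cox_fit(matrix(grp, ncol = 1), sv)
  expect_lt(abs(lr$p - cf$p), 0.02)
})
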