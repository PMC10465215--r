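test_that("AUC identities: perfect separation, label inversion, tie counting", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  a <- roc_auc(c(1, 3, 2, 5, 4, 6), c(0, 1, 0, 1, 0, 1))$auc
  b <- roc_auc(c(1, 3, 2, 5, 4, 6), c(1, 0, 1, 0, 1, 0))$auc
  expect_equal(a, 1 - b, tolerance = 1e-12)
  # tied toy: scores (1,2,2,3), labels (0,0,1,1); exhaustive pairs:
  # (2>1)=1, (2==2)=0.5, (3>1)=1, (3>2)=1 -> 3.5/4
  r <- roc_auc(c(1, 2, 2, 3), c(0, 0, 1, 1))
  expect_equal(r$auc, 3.5 / 4, tolerance = 1e-12)
  # curve anchors
  expect_equal(unlist(r$curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  # trapezoidal integral of the curve equals the pair-counting AUC
  trap <- sum(diff(r$curve$fpr) *
                (head(r$curve$tpr, -1) + tail(r$curve$tpr, -1)) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-12)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(2)
  s <- rnorm(60)
  y <- rbinom(60, 1, plogis(s))
  expect_equal(roc_auc(s, y)$auc, roc_auc(exp(s), y)$auc, tolerance = 1e-12)
})

test_that("rank-sum test: exact enumeration and normal approximation", {
  # (1,2,3) vs (4,5,6): 2 of the 20 assignments are as extreme -> p = 0.1
  r <- compare_groups(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_identical(r$method, "exact")
  # identical groups: p = 1 in exact mode
  r2 <- compare_groups(rep(c(3, 1, 4), 2), rep(c(0, 1), each = 3))
  expect_equal(r2$p, 1)
  # approximation close to exact for n = (8, 8)
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(16)
    g <- rep(0:1, each = 8)
    exact <- compare_groups(x, g)$p
    big <- compare_groups(c(x, rnorm(6) + 100), c(g, rep(0, 3), rep(1, 3)))
    expect_identical(big$method, "normal")
    approx_p <- {
      xx <- x; gg <- g
      r3 <- rank(xx)
      W <- sum(r3[gg == 1])
      mu <- 8 * 17 / 2
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(8 * 8 / 12 * 17)
      2 * pnorm(-abs(z))
    }
    expect_lt(abs(approx_p - exact), 0.02)
  }
  expect_error(compare_groups(1:5, c(0, 0, 0, 1, 1)), "at least 3")
})

test_that("logistic IRLS matches glm and detects separation", {
  set.seed(4)
  n <- 300
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + X[, "a"]))
  fit <- fit_logistic(X, y)
  ref <- glm(y ~ X, family = binomial)
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  # null DGP: coefficients near zero
  y0 <- rbinom(1000, 1, 0.5)
  X0 <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "x"))
  f0 <- fit_logistic(X0, y0)
  expect_true(all(abs(f0$coef) < 0.2))
  # perfectly balanced symmetric data: intercept 0
  # at x = +a, k of m respond; at x = -a, m - k of m respond
  xs <- c(rep(1, 4), rep(-1, 4), rep(2, 5), rep(-2, 5))
  ys <- c(1, 1, 1, 0,  0, 0, 0, 1,  1, 1, 1, 1, 0,  0, 0, 0, 0, 1)
  fs <- fit_logistic(matrix(xs, ncol = 1), ys)
  expect_lt(abs(fs$coef[1]), 1e-6)
  # complete separation raises the documented error; ridge mode recovers
  Xsep <- matrix(c(1:10), ncol = 1)
  ysep <- rep(c(0, 1), each = 5)
  expect_error(fit_logistic(Xsep, ysep), "separation")
  fr <- fit_logistic(Xsep, ysep, ridge = 0.5)
  expect_true(all(is.finite(fr$coef)))
  # rank-deficient design
  Xrd <- cbind(a = rnorm(30), b = 2 * 1:30, c = 1:30)
  expect_error(fit_logistic(Xrd, rbinom(30, 1, 0.5)), "rank-deficient")
})

test_that("nomogram points are anchored, normalized, and monotone in probability", {
  set.seed(5)
  n <- 400
  X <- cbind(p1 = runif(n, 0, 1), p2 = runif(n, 0, 1))
  y <- rbinom(n, 1, plogis(-0.5 + 1.0 * X[, 1] + 0.5 * X[, 2]))
  fit <- fit_logistic(X, y)
  # force the hand-example coefficients to make the identity exact
  fit$coef[] <- c(-0.5, 1, 0.5)
  sc <- nomogram_scale(fit, list(p1 = c(0, 1), p2 = c(0, 1)))
  expect_equal(sc$table$max_points[sc$table$predictor == "p1"], 100)
  expect_equal(sc$table$max_points[sc$table$predictor == "p2"], 50)
  expect_equal(sc$points("p2", 1), 50)
  expect_equal(sc$points("p1", 0), 0)
  # zero-coefficient predictor gets a flat zero-point line
  fit$coef[] <- c(-0.5, 1, 0)
  sc0 <- nomogram_scale(fit, list(p1 = c(0, 1), p2 = c(0, 1)))
  expect_equal(sc0$points("p2", 0.7), 0)
  # total points map monotonically to probability
  tp <- seq(0, 150, by = 10)
  expect_true(all(diff(sc$prob_at_points(tp)) > 0))
  expect_error(nomogram_scale(fit, list(p1 = c(0, 1), p2 = c(1, 1))),
               "range")
})

test_that("negative coefficients anchor points at the high end of the range", {
  set.seed(6)
  X <- cbind(risk = rnorm(200), protect = rnorm(200))
  y <- rbinom(200, 1, plogis(X[, 1] - X[, 2]))
  fit <- fit_logistic(X, y)
  sc <- nomogram_scale(fit, list(risk = c(-2, 2), protect = c(-2, 2)))
  # the protective predictor earns maximal points at its minimum value
  expect_equal(sc$points("protect", -2),
               sc$table$max_points[sc$table$predictor == "protect"],
               tolerance = 1e-9)
  expect_equal(sc$points("protect", 2), 0, tolerance = 1e-9)
})
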