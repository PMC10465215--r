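# Immunotherapy response evaluation: ROC/AUC by pair counting, Wilcoxon
# rank-sum comparison of scores between responders and non-responders,
# logistic fusion of HDS + CPS + MSI by IRLS, and a nomogram point scale.

#' ROC curve and AUC
#'
#' AUC via the Mann-Whitney pair-counting identity (ties count 1/2); the
#' curve comes from a threshold sweep over the unique scores and starts at
#' (0,0) and ends at (1,1). AUC is invariant under strictly increasing
#' transforms of the scores.
#'
#' @param scores numeric predictor (higher = more likely positive).
#' @param labels binary labels (0/1 or logical); both classes must be
#'   present.
#' @return list of class `roc_result`: `auc`, `curve` (data.frame fpr, tpr,
#'   threshold).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    hds_stop("labels must be binary 0/1", "hdscore_config_error")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    hds_stop("both classes must be present", "hdscore_config_error")
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  # rank-based pair counting (ties count 1/2)
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- t(vapply(thr, function(t) {
    c(fpr = sum(neg >= t) / n0, tpr = sum(pos >= t) / n1)
  }, c(fpr = 0, tpr = 0)))
  curve <- data.frame(fpr = curve[, "fpr"], tpr = curve[, "tpr"],
                      threshold = thr)
  structure(list(auc = auc, curve = curve), class = "roc_result")
}

# exact two-sided rank-sum p by complete enumeration of group assignments:
# p = P(|T - mu| >= |t_obs - mu|) over all choose(n, n1) assignments of the
# pooled ranks, mu the mean of the enumerated distribution
ranksum_exact_p <- function(ranks_pooled, n1, t_obs) {
  combos <- utils::combn(length(ranks_pooled), n1)
  stats_all <- colSums(matrix(ranks_pooled[combos], nrow = n1))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(t_obs - mu) - 1e-9)
}

#' Compare scores between two response groups (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum test. Exact enumeration of the permutation
#' distribution when both groups have at most 10 subjects; otherwise a
#' normal approximation with tie correction and 0.5 continuity correction.
#'
#' @param x numeric scores. @param group binary group indicator (0/1,
#'   logical, or two-level factor); each group needs >= 3 subjects.
#' @return list of class `ranksum_test`: `statistic` (rank sum of group 1),
#'   `p`, `method` ("exact" or "normal").
#' @export
compare_groups <- function(x, group) {
  g <- as.integer(factor(group)) - 1L
  if (length(unique(g)) != 2L)
    hds_stop("group must have exactly 2 levels", "hdscore_config_error")
  n1 <- sum(g == 1L); n0 <- sum(g == 0L)
  if (min(n1, n0) < 3L)
    hds_stop("each group needs at least 3 subjects", "hdscore_config_error")
  r <- rank(x, ties.method = "average")
  W <- sum(r[g == 1L])
  if (max(n1, n0) <= 10L) {
    p <- ranksum_exact_p(r, n1, W)
    method <- "exact"
  } else {
    n <- n1 + n0
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
    sigma2 <- n1 * n0 / 12 * ((n + 1) - tie_term)
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(statistic = W, p = min(p, 1), method = method,
                 n = c(n0 = n0, n1 = n1)),
            class = "ranksum_test")
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Fits `P(y=1) = plogis(intercept + X beta)` by IRLS; converges when the
#' relative log-likelihood change falls below `tol`. Complete separation
#' (coefficients diverging past |20|) raises an error advising ridge mode;
#' with `ridge > 0` a quadratic penalty `ridge/2 * ||beta||^2` (intercept
#' unpenalized) stabilizes the fit.
#'
#' @param design patients x predictors numeric matrix (no intercept column).
#' @param response binary 0/1 vector.
#' @param ridge L2 penalty (default 0 = maximum likelihood).
#' @param max_iter,tol IRLS controls.
#' @return list of class `logistic_fit`: `coef` (intercept first), `se`,
#'   `z`, `p`, `loglik`, `iterations`, `converged`, `fitted`.
#' @export
fit_logistic <- function(design, response, ridge = 0, max_iter = 100L,
                         tol = 1e-10) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(response)
  if (!all(y %in% c(0, 1)))
    hds_stop("response must be binary 0/1", "hdscore_config_error")
  if (nrow(X) <= ncol(X) + 1L)
    hds_stop("need more patients than predictors", "hdscore_config_error")
  if (any(apply(X, 2L, stats::sd) == 0))
    hds_stop("constant predictor column", "hdscore_config_error")
  Xd <- cbind(`(Intercept)` = 1, X)
  if (qr(Xd)$rank < ncol(Xd))
    hds_stop("rank-deficient design matrix", "hdscore_config_error")
  p <- ncol(Xd)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  beta <- numeric(p)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    wts <- pmax(mu * (1 - mu), 1e-10)
    info <- crossprod(Xd, Xd * wts) + pen
    score <- crossprod(Xd, y - mu) - pen %*% beta
    beta <- beta + drop(solve(info, score))
    if (any(abs(beta) > 20) && ridge == 0)
      hds_stop("complete separation detected (|coefficient| > 20); refit with ridge > 0",
               "hdscore_separation_error")
    ll <- sum(y * eta - log1p(exp(eta))) - ridge / 2 * sum(beta[-1L]^2)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) / (abs(ll_old) + 1e-10) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  eta <- drop(Xd %*% beta)
  mu <- stats::plogis(eta)
  wts <- pmax(mu * (1 - mu), 1e-10)
  vcov <- solve(crossprod(Xd, Xd * wts) + pen)
  se <- sqrt(diag(vcov))
  z <- beta / se
  structure(list(coef = stats::setNames(beta, colnames(Xd)), se = se,
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 loglik = sum(y * eta - log1p(exp(eta))),
                 iterations = it, converged = converged, ridge = ridge,
                 fitted = mu, predictors = colnames(X)),
            class = "logistic_fit")
}

#' Predict response probabilities from a logistic fit
#' @param fit [fit_logistic()] result. @param design new predictor matrix.
#' @return numeric probabilities.
#' @export
predict_logistic <- function(fit, design) {
  X <- as.matrix(design)
  stats::plogis(drop(cbind(1, X[, fit$predictors, drop = FALSE]) %*% fit$coef))
}

#' Nomogram point scale from a logistic model
#'
#' Each predictor k maps its value to
#' `points_k(x) = 100 * |beta_k| * (x - ref_k) / max_j(|beta_j| * range_j)`,
#' where `ref_k` is the range endpoint at which the predictor contributes
#' least to the response probability (the minimum for positive
#' coefficients, the maximum for negative ones), so points are always in
#' `[0, 100]` and increase with predicted probability. The predictor with
#' the largest `|beta| * range` spans exactly 0-100. Total points map
#' monotonically to predicted probability through the logistic link.
#'
#' @param fit a [fit_logistic()] result.
#' @param predictor_ranges named list/data.frame of `c(min, max)` per
#'   predictor (all ranges finite and positive width).
#' @return list of class `nomogram_scale`: per-predictor `points` functions
#'   (as slope/ref tables), `max_points`, and `prob_at_points(total)`.
#' @export
nomogram_scale <- function(fit, predictor_ranges) {
  stopifnot(inherits(fit, "logistic_fit"))
  preds <- fit$predictors
  if (!all(preds %in% names(predictor_ranges)))
    hds_stop("predictor_ranges must cover every model predictor",
             "hdscore_config_error")
  rng <- vapply(predictor_ranges[preds], function(r) {
    r <- range(as.numeric(r))
    if (!all(is.finite(r)) || diff(r) <= 0)
      hds_stop("zero or non-finite predictor range", "hdscore_config_error")
    r
  }, c(0, 0))
  beta <- fit$coef[preds]
  span <- abs(beta) * (rng[2L, ] - rng[1L, ])
  unit <- max(span) / 100  # linear-predictor units per point
  ref <- ifelse(beta >= 0, rng[1L, ], rng[2L, ])  # least-risk endpoint
  tab <- data.frame(predictor = preds, beta = as.numeric(beta),
                    min = rng[1L, ], max = rng[2L, ],
                    ref = ref, max_points = span / unit,
                    stringsAsFactors = FALSE)
  lp0 <- fit$coef[["(Intercept)"]] + sum(beta * ref)
  points_fun <- function(predictor, x) {
    i <- match(predictor, tab$predictor)
    if (is.na(i)) hds_stop("unknown predictor", "hdscore_config_error")
    abs(tab$beta[i]) * (ifelse(tab$beta[i] >= 0, x - tab$ref[i],
                               tab$ref[i] - x)) / unit
  }
  prob_at_points <- function(total) stats::plogis(lp0 + total * unit)
  structure(list(table = tab, unit = unit, lp0 = lp0,
                 points = points_fun, prob_at_points = prob_at_points),
            class = "nomogram_scale")
}
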