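# Cox proportional-hazards fitting (Newton-Raphson on the partial
# likelihood, Breslow or Efron ties), the Kaplan-Meier product-limit
# estimator, and the log-rank test.

# Partial log-likelihood, score and information at beta.
# X: n x p, ordered arbitrarily; time/event length n.
cox_loglik_parts <- function(beta, X, time, event, ties = "breslow") {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- pmin(pmax(eta, -500), 500)
  w <- exp(eta)
  # sort by decreasing time so risk sets are cumulative prefixes
  o <- order(time, decreasing = TRUE)
  Xo <- X[o, , drop = FALSE]; wo <- w[o]; to <- time[o]; eo <- event[o]
  S0 <- cumsum(wo)
  S1 <- apply(Xo * wo, 2L, cumsum)
  if (p == 1L) S1 <- matrix(S1, ncol = 1L)
  # S2 as n x p x p cumulative
  S2 <- array(0, c(n, p, p))
  for (a in seq_len(p)) for (b in a:p) {
    cs <- cumsum(Xo[, a] * Xo[, b] * wo)
    S2[, a, b] <- cs; S2[, b, a] <- cs
  }
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  ev_times <- unique(to[eo == 1])
  for (t in ev_times) {
    at_t <- which(to == t & eo == 1)      # tied events at this time
    d <- length(at_t)
    last <- max(which(to >= t))           # end of risk-set prefix
    s0 <- S0[last]
    s1 <- S1[last, ]
    s2 <- matrix(S2[last, , ], p, p)
    xi_sum <- colSums(Xo[at_t, , drop = FALSE])
    if (ties == "breslow" || d == 1L) {
      ll <- ll + sum(eta[o][at_t]) - d * log(s0)
      mu <- s1 / s0
      grad <- grad + xi_sum - d * mu
      info <- info + d * (s2 / s0 - tcrossprod(mu))
    } else {
      # Efron: average out the tied events' own contribution
      w_t <- wo[at_t]
      s0d <- sum(w_t)
      s1d <- colSums(Xo[at_t, , drop = FALSE] * w_t)
      s2d <- crossprod(Xo[at_t, , drop = FALSE] * sqrt(w_t))
      ll <- ll + sum(eta[o][at_t])
      for (r in seq_len(d) - 1L) {
        f <- r / d
        s0r <- s0 - f * s0d
        s1r <- s1 - f * s1d
        s2r <- s2 - f * s2d
        ll <- ll - log(s0r)
        mur <- s1r / s0r
        grad <- grad + xi_sum / d - mur
        info <- info + s2r / s0r - tcrossprod(mur)
      }
    }
  }
  list(loglik = ll, grad = grad, info = info)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Breslow (default) or Efron partial likelihood by
#' Newton-Raphson with step-halving on likelihood decrease. Convergence:
#' `max |score| < tol` or relative log-likelihood change `< tol`. A monotone
#' likelihood (perfect separation of events) is flagged non-converged with
#' coefficients capped at +-20.
#'
#' @param covariates numeric matrix (samples x p) or vector; column names
#'   become coefficient names.
#' @param surv a [survival_table()] (or data.frame with time/event) aligned
#'   with the covariate rows.
#' @param ties `"breslow"` or `"efron"`.
#' @param max_iter,tol Newton-Raphson controls.
#' @return list of class `cox_fit`: `beta`, `hr` (= exp(beta)), `se`, `z`,
#'   `p` (Wald), `ci_lower`/`ci_upper` (95%), `loglik`, `loglik_null`,
#'   `lrt_p`, `iterations`, `converged`.
#' @export
cox_fit <- function(covariates, surv, ties = c("breslow", "efron"),
                    max_iter = 50L, tol = 1e-9) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  time <- surv$time; event <- surv$event
  if (nrow(X) != length(time))
    hds_stop("covariate rows must match survival rows", "hdscore_config_error")
  if (sum(event) < 1)
    hds_stop("need at least one event", "hdscore_config_error")
  if (any(!is.finite(X)))
    hds_stop("covariates must be finite", "hdscore_config_error")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    hds_stop(sprintf("no variation in covariate '%s'",
                     colnames(X)[sds == 0][1L]), "hdscore_domain_error")
  if (nrow(X) <= ncol(X))
    hds_stop("need more observations than covariates", "hdscore_config_error")
  p <- ncol(X)
  beta <- numeric(p)
  parts <- cox_loglik_parts(beta, X, time, event, ties)
  ll0 <- parts$loglik
  converged <- FALSE
  it <- 0L
  capped <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    step <- tryCatch(solve(parts$info, parts$grad),
                     error = function(e) parts$grad / (diag(parts$info) + 1e-10))
    new_beta <- beta + step
    halvings <- 0L
    new_parts <- cox_loglik_parts(new_beta, X, time, event, ties)
    while (new_parts$loglik < parts$loglik && halvings < 30L) {
      halvings <- halvings + 1L
      new_beta <- beta + step / 2^halvings
      new_parts <- cox_loglik_parts(new_beta, X, time, event, ties)
    }
    rel_change <- abs(new_parts$loglik - parts$loglik) /
      (abs(parts$loglik) + 1e-10)
    beta <- new_beta
    parts <- new_parts
    if (any(abs(beta) > 20)) {  # monotone likelihood / separation
      beta <- pmin(pmax(beta, -20), 20)
      parts <- cox_loglik_parts(beta, X, time, event, ties)
      capped <- TRUE
      break
    }
    if (max(abs(parts$grad)) < tol || rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  se <- sqrt(diag(solve(parts$info)))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  structure(list(
    beta = stats::setNames(beta, colnames(X)),
    hr = exp(beta), se = se, z = z, p = pval,
    ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
    loglik = parts$loglik, loglik_null = ll0,
    lrt_p = stats::pchisq(2 * (parts$loglik - ll0), df = p,
                          lower.tail = FALSE),
    iterations = it, converged = converged && !capped, ties = ties
  ), class = "cox_fit")
}

#' Univariate Cox screen of genes for prognostic value
#'
#' Fits one univariate Cox model per gene on its z-scaled expression (so
#' hazard ratios are per standard deviation) and partitions genes at Wald
#' p < `alpha`: HR < 1 into protective set A, HR > 1 into risk set B,
#' everything else `none`. Genes whose fit fails are classed `none` with the
#' failure reason recorded.
#'
#' @param expr [expression_matrix()] or genes x samples matrix.
#' @param surv [survival_table()] aligned with the expression columns.
#' @param alpha Wald-p screening threshold (default 0.05).
#' @param ties passed to [cox_fit()].
#' @return data.frame of class `gene_screen_result`: gene, beta, hr, se, p,
#'   ci_lower, ci_upper, class (A/B/none), note.
#' @export
screen_prognostic <- function(expr, surv, alpha = 0.05,
                              ties = "breslow") {
  x <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  if (ncol(x) != nrow(surv))
    hds_stop("expression samples must align with the survival table",
             "hdscore_config_error")
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  res <- lapply(rownames(x), function(g) {
    v <- x[g, ]
    fit <- tryCatch(cox_fit(matrix(as.numeric(scale(v)), ncol = 1L,
                                   dimnames = list(NULL, g)),
                            surv, ties = ties),
                    error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(gene = g, beta = NA_real_, hr = NA_real_,
                        se = NA_real_, p = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, class = "none",
                        note = conditionMessage(fit),
                        stringsAsFactors = FALSE))
    cls <- if (!is.na(fit$p) && fit$p < alpha && fit$hr < 1) "A"
           else if (!is.na(fit$p) && fit$p < alpha && fit$hr > 1) "B"
           else "none"
    data.frame(gene = g, beta = fit$beta, hr = fit$hr, se = fit$se,
               p = fit$p, ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
               class = cls, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("gene_screen_result", "data.frame")
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' @param surv [survival_table()] (or data.frame with time/event).
#' @param groups optional per-sample group labels; one curve per group.
#' @return named list of data.frames (time, n_risk, n_event, n_censor,
#'   survival), one per group; class `km_curves`. Survival starts at 1 and
#'   is non-increasing.
#' @export
km_estimate <- function(surv, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", nrow(surv))
  groups <- as.character(groups)
  if (length(groups) != nrow(surv))
    hds_stop("groups must match the survival table", "hdscore_config_error")
  out <- lapply(split(seq_len(nrow(surv)), groups), function(idx) {
    if (length(idx) == 0L)
      hds_stop("group with zero subjects", "hdscore_config_error")
    tt <- surv$time[idx]; ee <- surv$event[idx]
    ts <- sort(unique(tt))
    n_risk <- vapply(ts, function(t) sum(tt >= t), 0)
    n_event <- vapply(ts, function(t) sum(tt == t & ee == 1), 0)
    n_censor <- vapply(ts, function(t) sum(tt == t & ee == 0), 0)
    s <- cumprod(1 - n_event / n_risk)
    data.frame(time = ts, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, survival = s)
  })
  structure(out, class = "km_curves")
}

#' Median survival time from a KM curve (first time S(t) <= 0.5)
#' @param curve one element of a [km_estimate()] result.
#' @return numeric; NA when the curve never reaches 0.5.
#' @export
km_median <- function(curve) {
  i <- which(curve$survival <= 0.5)
  if (length(i) == 0L) return(NA_real_)
  curve$time[i[1L]]
}

#' Log-rank test across groups
#'
#' Observed-minus-expected statistic with the hypergeometric variance;
#' df = number of groups - 1 (the first g-1 groups enter the quadratic form).
#'
#' @param surv [survival_table()]. @param groups per-sample group labels.
#' @return list(chisq, df, p, observed, expected), class `logrank_test`.
#' @export
logrank_test <- function(surv, groups) {
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  g <- length(gl)
  if (g < 2L)
    hds_stop("need at least 2 groups", "hdscore_config_error")
  if (any(table(groups) == 0L))
    hds_stop("group with zero subjects", "hdscore_config_error")
  tt <- surv$time; ee <- surv$event
  ev_times <- sort(unique(tt[ee == 1]))
  O <- stats::setNames(numeric(g), gl)
  E <- stats::setNames(numeric(g), gl)
  V <- matrix(0, g, g, dimnames = list(gl, gl))
  for (t in ev_times) {
    at_risk <- tt >= t
    n_t <- sum(at_risk)
    d_t <- sum(tt == t & ee == 1)
    n_gt <- vapply(gl, function(k) sum(at_risk & groups == k), 0)
    d_gt <- vapply(gl, function(k) sum(tt == t & ee == 1 & groups == k), 0)
    O <- O + d_gt
    E <- E + d_t * n_gt / n_t
    if (n_t > 1) {
      frac <- n_gt / n_t
      vt <- d_t * (n_t - d_t) / (n_t - 1) *
        (diag(frac, g) - tcrossprod(frac))
      V <- V + vt
    }
  }
  i <- seq_len(g - 1L)
  omE <- (O - E)[i]
  Vi <- V[i, i, drop = FALSE]
  chisq <- tryCatch(drop(t(omE) %*% solve(Vi, omE)),
                    error = function(e) 0)
  if (!is.finite(chisq) || chisq < 0) chisq <- 0
  p <- stats::pchisq(chisq, df = g - 1L, lower.tail = FALSE)
  structure(list(chisq = chisq, df = g - 1L, p = p,
                 observed = O, expected = E),
            class = "logrank_test")
}
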