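# Differential expression between subtypes: per-gene one-way F tests with
# empirical-Bayes variance moderation (the classical moderated-t construction
# extended to the omnibus F), and Benjamini-Hochberg adjustment.

# Invert the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# Method-of-moments fit (on the log scale) of a scaled inverse-chi-square
# prior to per-gene sample variances s2, each with df residual degrees of
# freedom. Returns prior df d0 (possibly Inf) and prior variance s0^2.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(df_prior = 0, s2_prior = NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- stats::var(e) * (sum(ok) - 1) / sum(ok)
  evar <- evar - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(ebar)
  }
  list(df_prior = d0, s2_prior = s0)
}

#' Moderated one-way ANOVA screen for subtype-associated genes
#'
#' Fits a per-gene one-way linear model across cluster labels and shrinks
#' the residual variances toward a common prior fitted by the method of
#' moments (scaled inverse chi-square, as in the moderated-t construction).
#' The moderated F statistic uses the posterior variance and an augmented
#' denominator df; p values are BH-adjusted across genes.
#'
#' Genes with zero within-cluster variance get p = 1 with a warning (never
#' NaN); a gene constant across all samples has F = 0 and p = 1.
#'
#' @param expr an [expression_matrix()] (log scale) or plain genes x samples
#'   matrix.
#' @param labels per-sample cluster labels (>= 2 clusters, each >= 2
#'   samples).
#' @param threshold adjusted-p significance threshold (default 0.01).
#' @param prior_df `"eb"` (default) to estimate the prior df empirically,
#'   or a number: 0 disables moderation (ordinary ANOVA F), `Inf` pools all
#'   genes to a common variance.
#' @param mode `"omnibus"` (one F across all clusters, default) or
#'   `"pairwise"` (smallest Bonferroni-adjusted pairwise moderated F p).
#' @return data.frame of class `deg_result`: gene, F, p, adj_p, per-cluster
#'   means, significant flag; attributes `df_prior`, `s2_prior`.
#' @export
moderated_anova <- function(expr, labels, threshold = 0.01,
                            prior_df = "eb",
                            mode = c("omnibus", "pairwise")) {
  mode <- match.arg(mode)
  x <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  labels <- as.character(labels)
  if (length(labels) != ncol(x))
    hds_stop("labels must match the number of samples", "hdscore_config_error")
  tab <- table(labels)
  if (length(tab) < 2L)
    hds_stop("need at least 2 clusters", "hdscore_config_error")
  if (any(tab < 2L))
    hds_stop(sprintf("cluster '%s' has fewer than 2 samples",
                     names(tab)[tab < 2L][1L]), "hdscore_config_error")
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  groups <- names(tab)
  n <- ncol(x); k <- length(groups)

  group_means <- vapply(groups, function(g)
    rowMeans(x[, labels == g, drop = FALSE]), numeric(nrow(x)))
  if (nrow(x) == 1L) group_means <- matrix(group_means, nrow = 1L)
  colnames(group_means) <- groups
  grand <- rowMeans(x)
  ssb <- as.numeric(group_means^2 %*% tab) - n * grand^2
  ssb <- pmax(ssb, 0)
  sst <- rowSums(x^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1
  df2 <- n - k
  s2 <- ssw / df2

  if (identical(prior_df, "eb")) {
    prior <- fit_variance_prior(s2, df2)
  } else {
    assert_scalar_number(prior_df, "prior_df", lower = 0)
    prior <- list(df_prior = prior_df,
                  s2_prior = if (prior_df > 0) mean(s2[s2 > 0]) else NA_real_)
  }
  d0 <- prior$df_prior; s0 <- prior$s2_prior

  posterior_var <- function(s2g) {
    if (d0 == 0) return(s2g)
    if (!is.finite(d0)) return(rep(s0, length(s2g)))
    (d0 * s0 + df2 * s2g) / (d0 + df2)
  }
  df_total <- if (is.finite(d0)) df2 + d0 else 1e6

  zero_var <- s2 <= 0
  if (mode == "omnibus") {
    s2post <- posterior_var(s2)
    Fstat <- (ssb / df1) / s2post
    p <- stats::pf(Fstat, df1, df_total, lower.tail = FALSE)
  } else {
    pairs <- utils::combn(groups, 2L, simplify = FALSE)
    s2post <- posterior_var(s2)
    pmat <- vapply(pairs, function(pr) {
      n1 <- tab[[pr[1L]]]; n2 <- tab[[pr[2L]]]
      delta <- group_means[, pr[1L]] - group_means[, pr[2L]]
      tstat <- delta / sqrt(s2post * (1 / n1 + 1 / n2))
      2 * stats::pt(-abs(tstat), df_total)
    }, numeric(nrow(x)))
    if (nrow(x) == 1L) pmat <- matrix(pmat, nrow = 1L)
    p <- pmin(apply(pmat, 1L, min) * length(pairs), 1)
    Fstat <- apply(pmat, 1L, function(z) max(-log10(z)))  # summary only
  }
  if (any(zero_var)) {
    exactly_constant <- zero_var & ssb <= 1e-12
    Fstat[zero_var] <- ifelse(exactly_constant[zero_var], 0, Fstat[zero_var])
    Fstat[zero_var & !exactly_constant] <- NA_real_
    p[zero_var] <- 1
    if (any(zero_var & !exactly_constant))
      warning(sprintf("%d gene(s) with zero within-cluster variance: p set to 1",
                      sum(zero_var & !exactly_constant)))
    Fstat[exactly_constant] <- 0
  }
  adj <- bh_adjust(p)
  res <- data.frame(gene = rownames(x), F = Fstat, p = p, adj_p = adj,
                    stringsAsFactors = FALSE)
  for (g in groups) res[[paste0("mean_", g)]] <- group_means[, g]
  res$significant <- res$adj_p < threshold
  attr(res, "df_prior") <- d0
  attr(res, "s2_prior") <- s0
  attr(res, "threshold") <- threshold
  class(res) <- c("deg_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p values in `[0, 1]`.
#' @return adjusted p values in the input order, monotone in rank order and
#'   capped at 1.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    hds_stop("p values must lie in [0, 1]", "hdscore_config_error")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}
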