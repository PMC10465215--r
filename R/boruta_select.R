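# Boruta all-relevant feature selection: every live feature gets a permuted
# "shadow" copy, a random forest is fit, and a feature scores a "hit" when
# its importance exceeds the maximum shadow importance. Hit counts are tested
# against Binomial(iterations, 1/2), two one-sided tests at alpha/2 with
# Bonferroni correction over the currently undecided features.
#
# Permutation importance is z-scored (divided by its standard error over
# trees), the importance measure of the original algorithm; confirmed
# features remain in subsequent forests, and the shadow pool never drops
# below 5 so the shadow maximum stays a meaningful null reference.

#' Configuration for Boruta feature selection
#'
#' @param n_trees trees per random forest (default 300).
#' @param max_iter maximum shadow iterations (default 100, minimum 5).
#' @param alpha two-sided significance level of the hit test (default 0.01).
#' @param importance `"permutation"` (default; less biased for correlated
#'   features) or `"impurity"`.
#' @param seed master seed; per-iteration forest seeds and shadow
#'   permutations derive from it.
#' @return list of class `boruta_config`.
#' @export
boruta_config <- function(n_trees = 300L, max_iter = 100L, alpha = 0.01,
                          importance = c("permutation", "impurity"),
                          seed = 1L) {
  importance <- match.arg(importance)
  assert_scalar_number(n_trees, "n_trees", lower = 10, integer = TRUE)
  assert_scalar_number(max_iter, "max_iter", lower = 5, integer = TRUE)
  assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  assert_scalar_number(seed, "seed", integer = TRUE)
  structure(list(n_trees = as.integer(n_trees),
                 max_iter = as.integer(max_iter), alpha = alpha,
                 importance = importance, seed = as.integer(seed)),
            class = "boruta_config")
}

#' Boruta all-relevant feature selection
#'
#' Iteratively compares random-forest feature importance against permuted
#' shadow copies. Features whose hit counts are binomially significantly
#' above 1/2 are confirmed; significantly below, rejected (and removed from
#' subsequent forests). Features still undecided after `max_iter` are
#' tentative; they are resolved by comparing each feature's median
#' importance against the median of the shadow-max history.
#'
#' @param X samples x features numeric matrix.
#' @param y categorical target (>= 2 classes, >= 5 samples per class).
#' @param config a [boruta_config()].
#' @return list of class `boruta_result`: per-feature `status`
#'   (confirmed/rejected/tentative before resolution), `resolved` status
#'   after tentative resolution, `hits`, `iterations` participated,
#'   `median_importance`, plus the `shadow_max` history.
#' @export
boruta_select <- function(X, y, config = boruta_config()) {
  stopifnot(inherits(config, "boruta_config"))
  X <- as.matrix(X)
  if (ncol(X) < 2L)
    hds_stop("need at least 2 features", "hdscore_config_error")
  if (any(!is.finite(X)))
    hds_stop("features must be finite", "hdscore_config_error")
  if (is.numeric(y) && !is.factor(y) && length(unique(y)) > 10L)
    hds_stop("y must be categorical (factor or few unique labels); use a discretized target",
             "hdscore_config_error")
  y <- factor(y)
  if (nlevels(y) < 2L || any(table(y) < 5L))
    hds_stop("y needs >= 2 classes with >= 5 samples each",
             "hdscore_config_error")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  feats <- colnames(X)
  nf <- length(feats)
  status <- stats::setNames(rep("undecided", nf), feats)
  hits <- stats::setNames(integer(nf), feats)
  iters <- stats::setNames(integer(nf), feats)
  imp_hist <- vector("list", nf); names(imp_hist) <- feats
  shadow_max_hist <- numeric(0)
  seeds <- child_seeds(config$seed, 2L * config$max_iter)

  for (it in seq_len(config$max_iter)) {
    live <- feats[status == "undecided"]
    if (length(live) == 0L) break
    in_forest <- feats[status != "rejected"]  # confirmed stay in the forest
    set.seed(seeds[2L * it - 1L])
    Xl <- X[, in_forest, drop = FALSE]
    shadow <- apply(Xl, 2L, sample)
    colnames(shadow) <- paste0(".shadow.", in_forest)
    if (ncol(shadow) < 5L) {  # keep at least 5 shadows for a stable maximum
      idx <- sample(ncol(Xl), 5L - ncol(shadow), replace = TRUE)
      extra <- apply(Xl[, idx, drop = FALSE], 2L, sample)
      colnames(extra) <- paste0(".shadowx.", seq_len(ncol(extra)))
      shadow <- cbind(shadow, extra)
    }
    dat <- data.frame(cbind(Xl, shadow), check.names = FALSE)
    dat$.y <- y
    rf <- ranger::ranger(
      dependent.variable.name = ".y", data = dat,
      num.trees = config$n_trees, importance = config$importance,
      scale.permutation.importance = config$importance == "permutation",
      seed = seeds[2L * it], num.threads = 1L,
      respect.unordered.factors = TRUE, verbose = FALSE)
    imp <- rf$variable.importance
    sh_max <- max(imp[grep("^\\.shadow", names(imp))])
    shadow_max_hist <- c(shadow_max_hist, sh_max)
    hit_now <- imp[live] > sh_max
    hits[live] <- hits[live] + as.integer(hit_now)
    iters[live] <- iters[live] + 1L
    for (f in live) imp_hist[[f]] <- c(imp_hist[[f]], imp[[f]])

    # binomial decision step, Bonferroni over undecided features
    m <- length(live)
    thr <- config$alpha / 2 / m
    p_high <- stats::pbinom(hits[live] - 1L, iters[live], 0.5,
                            lower.tail = FALSE)
    p_low <- stats::pbinom(hits[live], iters[live], 0.5)
    status[live[p_high < thr]] <- "confirmed"
    status[live[p_low < thr & p_high >= thr]] <- "rejected"
  }
  status[status == "undecided"] <- "tentative"

  med_imp <- vapply(imp_hist, function(v)
    if (length(v)) stats::median(v) else NA_real_, 0)
  resolved <- status
  tent <- names(status)[status == "tentative"]
  if (length(tent)) {
    sh_med <- stats::median(shadow_max_hist)
    resolved[tent] <- ifelse(med_imp[tent] > sh_med, "confirmed", "rejected")
  }
  structure(list(status = status, resolved = resolved, hits = hits,
                 iterations = iters, median_importance = med_imp,
                 shadow_max = shadow_max_hist, config = config),
            class = "boruta_result")
}

#' Features confirmed by Boruta (after tentative resolution)
#' @param result a [boruta_select()] result.
#' @param include_tentative use the resolved statuses (default TRUE).
#' @return character vector of confirmed feature names.
#' @export
boruta_confirmed <- function(result, include_tentative = TRUE) {
  st <- if (include_tentative) result$resolved else result$status
  names(st)[st == "confirmed"]
}
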