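# Non-negative matrix factorization with multi-restart consensus clustering.
#
# The factorization minimizes the Frobenius loss ||X - WH||_F^2 with the
# Lee-Seung multiplicative updates. Consensus clustering aggregates sample
# co-assignment frequencies over random restarts; the factorization rank is
# chosen by the cophenetic correlation of the consensus matrix.

#' Factorize a non-negative matrix by multiplicative updates
#'
#' Minimizes `||X - W H||_F^2` over element-wise non-negative `W` (genes x k)
#' and `H` (k x samples) with the Lee-Seung multiplicative update rules,
#' which guarantee a non-increasing loss. Denominators are protected by a
#' 1e-12 epsilon. Sample cluster memberships are the per-column argmax of H.
#'
#' @param X non-negative numeric matrix, no all-zero rows.
#' @param k factorization rank, `2 <= k < min(dim(X))` (k = 1 allowed for
#'   rank-1 checks).
#' @param seed integer seed for the uniform random initialization.
#' @param max_iter maximum number of update sweeps.
#' @param tol stop when the relative loss change per sweep falls below this.
#' @return list of class `nmf_fit`: `W`, `H`, `loss_trace` (Frobenius error
#'   per iteration), `converged`, `iterations`, `seed`, `labels`.
#' @export
nmf_factorize <- function(X, k, seed = 1L, max_iter = 500L, tol = 1e-6) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(X < 0))
    hds_stop("X must be finite and non-negative", "hdscore_domain_error")
  if (any(rowSums(X) == 0))
    hds_stop("X has all-zero rows; drop them before factorizing",
             "hdscore_domain_error")
  assert_scalar_number(k, "k", lower = 1, integer = TRUE)
  if (k >= min(dim(X)) && k != 1L)
    hds_stop(sprintf("k = %d out of range for a %d x %d matrix", k,
                     nrow(X), ncol(X)), "hdscore_config_error")
  eps <- 1e-12
  set.seed(seed)
  W <- matrix(stats::runif(nrow(X) * k, 0.1, 1), nrow(X), k)
  H <- matrix(stats::runif(k * ncol(X), 0.1, 1), k, ncol(X))
  loss <- numeric(max_iter)
  prev <- Inf
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    H <- H * (crossprod(W, X)) / (crossprod(W, W %*% H) + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    loss[it] <- sqrt(sum((X - W %*% H)^2))
    if (is.finite(prev) && prev > 0 &&
        abs(prev - loss[it]) / prev < tol) {
      converged <- TRUE
      break
    }
    prev <- loss[it]
  }
  labels <- apply(H, 2L, which.max)
  structure(list(W = W, H = H, loss_trace = loss[seq_len(it)],
                 converged = converged, iterations = it,
                 seed = as.integer(seed), labels = labels),
            class = "nmf_fit")
}

# mean silhouette width of labels under distance matrix d (plain matrix)
mean_silhouette <- function(d, labels) {
  n <- length(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(ks[ks != labels[i]],
                    function(kk) mean(d[i, labels == kk]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Consensus NMF clustering with rank selection
#'
#' For each candidate rank k, runs `n_runs` factorizations from distinct
#' seeds and records the fraction of runs in which each sample pair lands in
#' the same argmax cluster (the consensus matrix). The rank maximizing the
#' cophenetic correlation of its consensus matrix is chosen (ties broken
#' toward the smaller k) and final labels come from an average-linkage
#' hierarchical cut of `1 - consensus`.
#'
#' Log-scale matrices with negative entries are shifted by subtracting the
#' global minimum before factorization.
#'
#' @param X numeric matrix (genes x samples); may contain negative values
#'   (shifted internally).
#' @param k_range candidate ranks (default 2:5).
#' @param n_runs restarts per rank (default 300; use fewer for testing).
#' @param seed master seed; per-run seeds are derived from it.
#' @param max_iter,tol passed to [nmf_factorize()].
#' @param min_cluster_size ranks whose consensus cut produces a cluster
#'   smaller than this are excluded from rank selection (their metrics are
#'   still reported). Default 1 = no restriction; the pipeline uses 5 so
#'   every subtype can feed the downstream per-cluster statistics. If no
#'   rank qualifies, the restriction is dropped.
#' @return list of class `consensus_result`: `chosen_k`, `labels`, and
#'   per-rank `consensus` matrices, `cophenetic` and `silhouette` values,
#'   and the reconstruction `error` of the best restart.
#' @export
consensus_cluster <- function(X, k_range = 2:5, n_runs = 300L, seed = 1L,
                              max_iter = 200L, tol = 1e-5,
                              min_cluster_size = 1L) {
  X <- as.matrix(X)
  if (any(!is.finite(X)))
    hds_stop("X must be finite", "hdscore_domain_error")
  assert_scalar_number(n_runs, "n_runs", lower = 1, integer = TRUE)
  if (min(X) < 0) X <- X - min(X)
  if (any(colSums(X) == 0))
    hds_stop("constant-zero sample column after shifting", "hdscore_domain_error")
  n <- ncol(X)
  seeds <- child_seeds(seed, length(k_range) * n_runs)
  per_k <- vector("list", length(k_range))
  names(per_k) <- as.character(k_range)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    co <- matrix(0, n, n)
    best_err <- Inf
    for (r in seq_len(n_runs)) {
      fit <- nmf_factorize(X, k, seed = seeds[(ki - 1L) * n_runs + r],
                           max_iter = max_iter, tol = tol)
      lab <- fit$labels
      co <- co + outer(lab, lab, "==")
      err <- fit$loss_trace[length(fit$loss_trace)]
      if (err < best_err) best_err <- err
    }
    co <- co / n_runs
    dimnames(co) <- list(colnames(X), colnames(X))
    dis <- stats::as.dist(1 - co)
    hc <- stats::hclust(dis, method = "average")
    coph <- suppressWarnings(stats::cor(dis, stats::cophenetic(hc)))
    if (!is.finite(coph)) coph <- 1  # all pairs identical -> perfect consensus
    lab_k <- stats::cutree(hc, k = min(k, n))
    per_k[[ki]] <- list(k = k, consensus = co, cophenetic = coph,
                        silhouette = mean_silhouette(1 - co, lab_k),
                        error = best_err, labels = lab_k, hclust = hc)
  }
  coph_all <- vapply(per_k, `[[`, 0, "cophenetic")
  min_size <- vapply(per_k, function(z) min(table(z$labels)), 0)
  eligible <- min_size >= min_cluster_size
  if (!any(eligible)) eligible[] <- TRUE
  # first maximum among eligible ranks -> ties break toward the smaller k
  chosen <- k_range[eligible][which.max(coph_all[eligible])]
  structure(list(
    chosen_k = chosen,
    labels = per_k[[as.character(chosen)]]$labels,
    k_range = k_range,
    cophenetic = coph_all,
    silhouette = vapply(per_k, `[[`, 0, "silhouette"),
    error = vapply(per_k, `[[`, 0, "error"),
    consensus = lapply(per_k, `[[`, "consensus")
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result>\n  k:          ",
      paste(x$k_range, collapse = "  "), "\n  cophenetic: ",
      paste(sprintf("%.3f", x$cophenetic), collapse = "  "),
      "\n  chosen_k:   ", x$chosen_k, "\n")
  invisible(x)
}
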