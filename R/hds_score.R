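# The HDAC score (HDS): per-gene-set PCA on training data, per-sample PC1
# projections, HDS = score(protective set A) - score(risk set B), and a
# median dichotomization into high/low groups.
#
# The PC1 sign is indeterminate; each set's loading is oriented so that the
# per-sample set score correlates positively with the set's mean z-scaled
# expression ("high program expression -> high score"). Scoring new samples
# reuses the training centering/scaling, loadings and median.

fit_set_pca <- function(zmat, set_name) {
  # zmat: samples x genes, already z-scaled on training data
  pc <- stats::prcomp(zmat, center = FALSE, scale. = FALSE)
  loading <- pc$rotation[, 1L]
  loading <- loading / sqrt(sum(loading^2))
  scores <- drop(zmat %*% loading)
  orient <- stats::cor(scores, rowMeans(zmat))
  sign_ <- if (is.na(orient) || orient >= 0) 1 else -1
  list(loading = loading, sign = sign_)
}

#' Fit an HDS scoring model from protective and risk gene sets
#'
#' Z-scales each set's genes on the training cohort, runs one PCA per set on
#' the samples x genes submatrix, stores the unit-norm PC1 loading with an
#' orientation sign (positive correlation with the set's mean z-expression),
#' and records the training-cohort median HDS used for dichotomization.
#'
#' @param expr [expression_matrix()] (log scale) or genes x samples matrix.
#' @param setA protective gene set (univariate HR < 1), >= 2 genes.
#' @param setB risk gene set (HR > 1), >= 2 genes; disjoint from `setA`
#'   (overlap triggers a warning, not an error, for sensitivity checks).
#' @param method `"separate"` (default: one PCA per set, the gene-signature
#'   convention) or `"joint"` (single PCA on the union, oriented by the
#'   A-minus-B mean contrast).
#' @return list of class `hds_model`.
#' @export
fit_hds <- function(expr, setA, setB, method = c("separate", "joint")) {
  method <- match.arg(method)
  x <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  missing <- setdiff(c(setA, setB), rownames(x))
  if (length(missing))
    hds_stop(sprintf("gene(s) not in expression matrix: %s",
                     paste(missing, collapse = ", ")),
             "hdscore_config_error")
  if (length(setA) < 2L || length(setB) < 2L)
    hds_stop("each gene set needs at least 2 genes", "hdscore_config_error")
  if (length(intersect(setA, setB)) &&
      !identical(sort(setA), sort(setB)))
    warning("setA and setB overlap")
  drop_zero_var <- function(genes) {
    sds <- apply(x[genes, , drop = FALSE], 1L, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping %d zero-variance gene(s) from a set",
                      sum(sds == 0)))
      genes <- genes[sds > 0]
    }
    if (length(genes) < 2L)
      hds_stop("fewer than 2 usable genes left in a set",
               "hdscore_config_error")
    genes
  }
  setA <- drop_zero_var(setA); setB <- drop_zero_var(setB)
  zA <- zscale_cols(t(x[setA, , drop = FALSE]))
  zB <- zscale_cols(t(x[setB, , drop = FALSE]))
  if (method == "separate") {
    pcA <- fit_set_pca(zA$scaled, "A")
    pcB <- fit_set_pca(zB$scaled, "B")
  } else {
    zjoint <- cbind(zA$scaled, zB$scaled)
    pc <- stats::prcomp(zjoint, center = FALSE, scale. = FALSE)
    loading <- pc$rotation[, 1L] / sqrt(sum(pc$rotation[, 1L]^2))
    contrast <- rowMeans(zA$scaled) - rowMeans(zB$scaled)
    s <- stats::cor(drop(zjoint %*% loading), contrast)
    s <- if (is.na(s) || s >= 0) 1 else -1
    pcA <- list(loading = loading[seq_along(setA)], sign = s)
    pcB <- list(loading = -loading[length(setA) + seq_along(setB)], sign = s)
  }
  model <- structure(list(
    setA = setA, setB = setB, method = method,
    centerA = zA$center, scaleA = zA$scale,
    centerB = zB$center, scaleB = zB$scale,
    loadingA = pcA$loading, signA = pcA$sign,
    loadingB = pcB$loading, signB = pcB$sign,
    median_hds = NA_real_
  ), class = "hds_model")
  model$median_hds <- stats::median(score_hds(model, expr)$hds)
  model
}

#' Score samples with a fitted HDS model
#'
#' Centers and scales new samples with the training parameters, projects
#' onto each set's oriented PC1 loading, and returns
#' `hds = pc1A - pc1B` with a high/low group call at the training median
#' (scores strictly above the median are "high"; exact-median ties go to
#' "low").
#'
#' @param model an [fit_hds()] model. @param expr expression for the samples
#'   to score; must contain all model genes.
#' @return data.frame of class `hds_scores`: sample, pc1A, pc1B, hds, group.
#' @export
score_hds <- function(model, expr) {
  stopifnot(inherits(model, "hds_model"))
  x <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  missing <- setdiff(c(model$setA, model$setB), rownames(x))
  if (length(missing))
    hds_stop(sprintf("model gene(s) missing from expression: %s",
                     paste(missing, collapse = ", ")),
             "hdscore_config_error")
  project <- function(genes, ctr, scl, loading, sign_) {
    z <- sweep(sweep(t(x[genes, , drop = FALSE]), 2L, ctr, "-"),
               2L, scl, "/")
    sign_ * drop(z %*% loading)
  }
  pc1A <- project(model$setA, model$centerA, model$scaleA,
                  model$loadingA, model$signA)
  pc1B <- project(model$setB, model$centerB, model$scaleB,
                  model$loadingB, model$signB)
  hds <- pc1A - pc1B
  group <- if (is.na(model$median_hds)) rep(NA_character_, length(hds))
           else dichotomize_median(hds, median_from = model$median_hds)
  structure(data.frame(sample = colnames(x), pc1A = pc1A, pc1B = pc1B,
                       hds = hds, group = group, stringsAsFactors = FALSE),
            class = c("hds_scores", "data.frame"))
}

#' Median split of scores into high/low groups
#'
#' `high` iff score > median; samples exactly at the median are assigned
#' `low` (borderline patients are conservatively not called high).
#'
#' @param scores numeric vector (>= 2 values).
#' @param median_from median to split at; default the median of `scores`
#'   themselves (supply the training median to score new cohorts).
#' @return character vector of `"high"` / `"low"`.
#' @export
dichotomize_median <- function(scores, median_from = NULL) {
  if (is.null(median_from) && length(scores) < 2L)
    hds_stop("need at least 2 scores to define a median split",
             "hdscore_config_error")
  med <- if (is.null(median_from)) stats::median(scores) else median_from
  if (length(scores) > 1L && all(scores == scores[1L]))
    warning("all scores identical; every sample assigned to the low group")
  ifelse(scores > med, "high", "low")
}

#' Spearman correlation of HDS with signature enrichment scores
#'
#' Mid-rank Spearman correlation with a t-approximation p value, one row per
#' signature. Constant vectors yield NA (undefined rank correlation).
#'
#' @param hds numeric vector of per-sample scores (or an `hds_scores`
#'   data.frame).
#' @param enrich signature x sample matrix aligned with `hds`.
#' @return data.frame: signature, rho, p.
#' @export
correlate_with_signatures <- function(hds, enrich) {
  if (inherits(hds, "hds_scores")) hds <- hds$hds
  enrich <- as.matrix(enrich)
  if (length(hds) != ncol(enrich))
    hds_stop("hds length must match enrichment columns",
             "hdscore_config_error")
  if (length(hds) < 5L)
    hds_stop("need at least 5 paired samples", "hdscore_config_error")
  if (is.null(rownames(enrich)))
    rownames(enrich) <- paste0("sig", seq_len(nrow(enrich)))
  res <- t(vapply(seq_len(nrow(enrich)), function(i) {
    st <- spearman_test(hds, enrich[i, ])
    c(rho = st$rho, p = st$p)
  }, c(rho = 0, p = 0)))
  data.frame(signature = rownames(enrich), rho = res[, "rho"],
             p = res[, "p"], stringsAsFactors = FALSE)
}

#' Serialize an HDS model to a JSON text file
#' @param model `hds_model`. @param path output path.
#' @export
write_hds_model <- function(model, path) {
  stopifnot(inherits(model, "hds_model"))
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an HDS model from JSON
#' @param path file written by [write_hds_model()].
#' @return `hds_model`.
#' @export
read_hds_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("centerA", "scaleA", "centerB", "scaleB",
              "loadingA", "loadingB"))
    obj[[f]] <- stats::setNames(as.numeric(obj[[f]]), names(obj[[f]]))
  structure(obj, class = "hds_model")
}
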