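# Single-sample gene-set enrichment (ssGSEA): per sample, genes are ranked
# by expression and a weighted running sum is integrated over the ranked
# list. Member positions accumulate weight rank^alpha (normalized over the
# set); non-member positions accumulate 1/(N - m). The score is the sum of
# the running difference over all positions, so it depends only on
# within-sample ranks.

#' ssGSEA enrichment score of one gene set in one sample
#'
#' Genes are ranked by expression within the sample: the walk order is
#' decreasing expression with stable input order on ties, while the rank
#' statistic uses mid-ranks (largest expression = rank N). At each position
#' the running in-set weight (|rank|^alpha over members, normalized to sum
#' to 1) minus the out-of-set weight (1/(N-m) per non-member) is
#' accumulated; the score is the sum over all N positions (the integrated
#' enrichment score of the ssGSEA convention).
#'
#' @param expr_column named numeric vector: one sample's expression.
#' @param gene_set character vector of gene ids.
#' @param alpha rank-weighting exponent (default 0.25; 0 gives uniform
#'   member weights).
#' @return numeric score; NA with a warning when the set does not intersect
#'   the expressed genes.
#' @export
ssgsea_sample <- function(expr_column, gene_set, alpha = 0.25) {
  genes <- names(expr_column)
  if (is.null(genes))
    hds_stop("expr_column must be a named vector", "hdscore_config_error")
  member <- genes %in% gene_set
  m <- sum(member)
  if (m == 0L) {
    warning("gene set does not intersect the expressed genes; score is NA")
    return(NA_real_)
  }
  N <- length(genes)
  r <- rank(expr_column, ties.method = "average")  # mid-ranks, max = highest
  ord <- order(-expr_column)                       # stable on ties
  member_o <- member[ord]
  w <- ifelse(member_o, r[ord]^alpha, 0)
  w_sum <- sum(w)
  p_in <- cumsum(w) / w_sum
  p_out <- if (N == m) rep(0, N) else cumsum(!member_o) / (N - m)
  sum(p_in - p_out)
}

#' ssGSEA scores for a gene-set collection across all samples
#'
#' @param expr [expression_matrix()] or genes x samples matrix.
#' @param collection a [gene_set_collection()] (or named list of gene ids).
#' @param alpha rank-weighting exponent, see [ssgsea_sample()].
#' @param normalize `"raw"` (default) or `"range"`: divide the whole matrix
#'   by its global max minus global min (the cross-cohort comparison
#'   convention).
#' @return signature x sample numeric matrix, attribute
#'   `normalization`.
#' @export
score_collection <- function(expr, collection, alpha = 0.25,
                             normalize = c("raw", "range")) {
  normalize <- match.arg(normalize)
  x <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  if (length(collection) < 1L)
    hds_stop("need at least one signature", "hdscore_config_error")
  out <- matrix(NA_real_, nrow = length(collection), ncol = ncol(x),
                dimnames = list(names(collection), colnames(x)))
  for (j in seq_len(ncol(x))) {
    col <- stats::setNames(x[, j], rownames(x))
    for (i in seq_along(collection))
      out[i, j] <- ssgsea_sample(col, collection[[i]], alpha = alpha)
  }
  if (normalize == "range") {
    rng <- range(out, na.rm = TRUE)
    if (diff(rng) > 0) out <- out / diff(rng)
  }
  attr(out, "normalization") <- normalize
  out
}
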