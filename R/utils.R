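# Internal helpers shared across modules.

#' Stop with a classed condition
#' @noRd
hds_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "hdscore_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    hds_stop(sprintf("'%s' must be a single finite number", name),
             "hdscore_config_error")
  if (x < lower || x > upper)
    hds_stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                     format(lower), format(upper), format(x)),
             "hdscore_config_error")
  if (integer && x != round(x))
    hds_stop(sprintf("'%s' must be an integer, got %s", name, format(x)),
             "hdscore_config_error")
  invisible(x)
}

#' Column-wise z-scaling that tolerates zero-variance columns
#'
#' @param x numeric matrix (observations x variables).
#' @return list with `scaled`, `center`, `scale` (zero-variance columns get
#'   scale 1 so they map to all-zero columns).
#' @noRd
zscale_cols <- function(x) {
  ctr <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  list(scaled = sweep(sweep(x, 2L, ctr, "-"), 2L, sd_, "/"),
       center = ctr, scale = sd_)
}

#' Adjusted Rand index between two label vectors
#'
#' Measures agreement between two partitions, corrected for chance; 1 means
#' identical partitions (up to label permutation), 0 is the expected value
#' under independent random labelings.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    hds_stop("label vectors must have equal length", "hdscore_config_error")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Spearman correlation with mid-ranks and t-approximation p value
#'
#' @param x,y numeric vectors, equal length, no NA.
#' @return list(rho, p); rho is NA with p NA when either vector is constant.
#' @noRd
spearman_test <- function(x, y) {
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Derive a stream of child seeds from one master seed
#' @noRd
child_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
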