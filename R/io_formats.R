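# Tabular IO: expression TSV, clinical TSV, GMT gene sets, unit conversion.
#
# All files are UTF-8, tab-separated, '.' decimal. Missing expression values
# are rejected rather than imputed.

EXPRESSION_UNITS <- c("FPKM", "TPM", "LOG2_TPM_PLUS1", "ARBITRARY_LOG")

#' Construct an expression matrix container
#'
#' A thin S3 wrapper around a genes x samples numeric matrix carrying a
#' declared expression unit. Raw units (FPKM, TPM) require non-negative
#' values; log units may be negative.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param unit one of `"FPKM"`, `"TPM"`, `"LOG2_TPM_PLUS1"`, `"ARBITRARY_LOG"`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, unit) {
  unit <- match.arg(unit, EXPRESSION_UNITS)
  if (!is.matrix(values) || !is.numeric(values))
    hds_stop("'values' must be a numeric matrix", "hdscore_parse_error")
  g <- rownames(values); s <- colnames(values)
  if (is.null(g) || is.null(s))
    hds_stop("expression matrix needs gene rownames and sample colnames",
             "hdscore_parse_error")
  g <- trimws(g); s <- trimws(s)
  if (anyDuplicated(g))
    hds_stop("duplicate gene identifiers", "hdscore_parse_error")
  if (anyDuplicated(s))
    hds_stop("duplicate sample identifiers", "hdscore_parse_error")
  if (anyNA(values) || !all(is.finite(values)))
    hds_stop("expression values must be finite (no NA); imputation is not supported",
             "hdscore_parse_error")
  if (unit %in% c("FPKM", "TPM") && any(values < 0))
    hds_stop(sprintf("unit %s implies non-negative values", unit),
             "hdscore_parse_error")
  dimnames(values) <- list(g, s)
  structure(list(values = values, unit = unit), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, unit %s\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column holds gene identifiers, header row holds sample identifiers.
#' Duplicate gene ids are collapsed by the element-wise maximum (a message
#' reports how many).
#'
#' @param path file path.
#' @param unit declared unit of the stored values (see [expression_matrix()]).
#' @return `expression_matrix`.
#' @export
read_expression <- function(path, unit) {
  unit <- match.arg(unit, EXPRESSION_UNITS)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L)
    hds_stop(sprintf("'%s': need a header line and at least one gene row", path),
             "hdscore_parse_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncol_expect <- length(header)
  samples <- trimws(header[-1L])
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != ncol_expect))
    hds_stop(sprintf("'%s': ragged row at line %d (%d fields, expected %d)",
                     path, which(nf != ncol_expect)[1L] + 1L,
                     nf[nf != ncol_expect][1L], ncol_expect),
             "hdscore_parse_error")
  genes <- trimws(vapply(body, `[[`, "", 1L))
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(ncol_expect - 1L))
  )
  vals <- matrix(vals, nrow = ncol_expect - 1L)  # samples x genes for now
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1L]
    hds_stop(sprintf("'%s': non-numeric cell at line %d", path, bad + 1L),
             "hdscore_parse_error")
  }
  m <- t(vals)
  if (anyDuplicated(genes)) {
    ndup <- sum(duplicated(genes))
    m <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i) {
      if (length(i) == 1L) m[i, , drop = TRUE]
      else apply(m[i, , drop = FALSE], 2L, max)
    }))
    message(sprintf("read_expression: collapsed %d duplicate gene id(s) by max", ndup))
    genes <- rownames(m) <- sort(unique(genes))  # split() orders by name
  }
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, unit)
}

#' Write an expression matrix to TSV
#'
#' Values are printed with 15 significant digits so that read/write round
#' trips are lossless at 12 significant digits.
#'
#' @param m `expression_matrix`.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(m$values)), collapse = "\t"), con)
  body <- apply(m$values, 1L, function(v)
    paste(format(v, digits = 15, scientific = FALSE, trim = TRUE),
          collapse = "\t"))
  writeLines(paste(rownames(m$values), body, sep = "\t"), con)
  invisible(path)
}

#' Construct / validate a survival table
#'
#' @param data data.frame with columns `sample`, `time` (> 0), `event`
#'   (0/1), plus optional covariate columns.
#' @return data.frame of class `survival_table`.
#' @export
survival_table <- function(data) {
  need <- c("sample", "time", "event")
  if (!all(need %in% names(data)))
    hds_stop("survival table needs columns sample, time, event",
             "hdscore_parse_error")
  data$sample <- trimws(as.character(data$sample))
  if (anyDuplicated(data$sample))
    hds_stop("duplicate sample ids in survival table", "hdscore_parse_error")
  if (anyNA(data$time) || any(data$time <= 0))
    hds_stop("survival times must be positive", "hdscore_parse_error")
  if (!all(data$event %in% c(0, 1)))
    hds_stop("event indicator must be 0/1", "hdscore_parse_error")
  class(data) <- c("survival_table", "data.frame")
  data
}

#' Read a clinical / survival TSV (sample, time, event, covariates...)
#' @param path file path.
#' @return `survival_table`.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  survival_table(df)
}

#' Write a survival table to TSV
#' @param surv `survival_table`. @param path output path.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert FPKM to TPM
#'
#' Per sample j: `TPM_gj = FPKM_gj / sum_g FPKM_gj * 1e6`, so every output
#' column sums to one million. Re-normalizing a TPM matrix is a no-op.
#'
#' @param m `expression_matrix` with unit FPKM (or TPM, for re-normalization).
#' @return `expression_matrix` with unit TPM.
#' @export
fpkm_to_tpm <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!m$unit %in% c("FPKM", "TPM"))
    hds_stop("fpkm_to_tpm expects a raw-unit (FPKM/TPM) matrix",
             "hdscore_config_error")
  cs <- colSums(m$values)
  if (any(cs == 0)) {
    bad <- colnames(m$values)[cs == 0]
    hds_stop(sprintf("all-zero expression column(s): %s",
                     paste(bad, collapse = ", ")),
             "hdscore_conversion_error")
  }
  expression_matrix(sweep(m$values, 2L, cs, "/") * 1e6, "TPM")
}

#' Element-wise log2(x + 1) transform
#'
#' @param m raw-unit `expression_matrix`.
#' @return `expression_matrix` with unit LOG2_TPM_PLUS1 (for TPM input) or
#'   ARBITRARY_LOG otherwise.
#' @export
log2p1 <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!m$unit %in% c("FPKM", "TPM"))
    hds_stop("log2p1 expects a raw-unit matrix", "hdscore_config_error")
  unit <- if (m$unit == "TPM") "LOG2_TPM_PLUS1" else "ARBITRARY_LOG"
  expression_matrix(log2(m$values + 1), unit)
}

#' Read a GMT gene-set collection
#'
#' Each line: set name, description, then one or more gene ids, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors (class `gene_set_collection`);
#'   descriptions kept in attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    hds_stop(sprintf("'%s': GMT line %d has %d field(s), need at least 3",
                     path, which(nf < 3L)[1L], nf[nf < 3L][1L]),
             "hdscore_parse_error")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    hds_stop(sprintf("duplicate gene-set name '%s'", nm[duplicated(nm)][1L]),
             "hdscore_parse_error")
  sets <- lapply(fields, function(f) trimws(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets,
                      description = vapply(fields, `[[`, "", 2L))
}

#' Construct a gene-set collection
#' @param sets named list of character vectors (unique names, non-empty sets).
#' @param description optional character vector of the same length.
#' @return classed named list.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    hds_stop("gene-set names must be present and unique", "hdscore_parse_error")
  if (any(lengths(sets) == 0L))
    hds_stop("empty gene set", "hdscore_parse_error")
  structure(sets, description = description,
            class = c("gene_set_collection", "list"))
}

#' Write a gene-set collection to GMT
#' @param collection `gene_set_collection`. @param path output path.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "description")
  if (is.null(desc)) desc <- rep("na", length(collection))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(collection), desc, collection)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Intersect an expression matrix and survival table on sample ids
#'
#' Pipeline stages operate on the intersection of expression and clinical
#' sample ids; dropped samples are reported with a warning.
#'
#' @param expr `expression_matrix`. @param surv `survival_table`.
#' @return list(expr, surv) restricted to shared samples, same order.
#' @export
align_samples <- function(expr, surv) {
  shared <- intersect(colnames(expr$values), surv$sample)
  if (length(shared) == 0L)
    hds_stop("no shared samples between expression and survival table",
             "hdscore_config_error")
  drop_e <- setdiff(colnames(expr$values), shared)
  drop_s <- setdiff(surv$sample, shared)
  if (length(drop_e) || length(drop_s))
    warning(sprintf("align_samples: dropping %d expression-only and %d clinical-only sample(s)",
                    length(drop_e), length(drop_s)))
  expr$values <- expr$values[, shared, drop = FALSE]
  surv <- surv[match(shared, surv$sample), , drop = FALSE]
  rownames(surv) <- NULL
  list(expr = expr, surv = surv)
}
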