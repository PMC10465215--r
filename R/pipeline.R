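# End-to-end orchestration: consensus-NMF subtyping on the regulator panel,
# moderated-F DEG screen between subtypes, univariate Cox prognostic screen,
# Boruta reduction, A/B partition by hazard-ratio sign, HDS fitting and
# scoring, survival contrast of high vs low HDS, optional signature
# correlation and response evaluation. Every stage logs parameters, seeds
# and gene counts; all outputs are tab-separated text plus a JSON model.

#' Assemble a pipeline configuration
#'
#' Inputs may be file paths (expression TSV, clinical TSV, regulator gene
#' list, GMT) or in-memory objects; see [run_pipeline()]. Stage parameters
#' default to the package's standard screen: DEG adjusted-p threshold 0.01,
#' Cox alpha 0.05, consensus NMF over k = 2..5.
#'
#' @param expression [expression_matrix()] or TSV path.
#' @param clinical [survival_table()] or TSV path.
#' @param regulator_genes character vector of panel gene ids, or a path to a
#'   one-id-per-line file.
#' @param gene_sets optional [gene_set_collection()] or GMT path for
#'   signature correlation.
#' @param response optional data.frame with per-sample `cps`, `msi`,
#'   `response` columns for response evaluation.
#' @param expression_unit declared unit when `expression` is a path.
#' @param k_range,n_runs consensus NMF controls.
#' @param deg_threshold adjusted-p cutoff for the DEG stage.
#' @param cox_alpha Wald-p cutoff for the prognostic screen.
#' @param boruta a [boruta_config()].
#' @param ssgsea_alpha rank-weight exponent for signature scoring.
#' @param seed master seed for all stochastic stages.
#' @param outdir output directory (created if absent).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, clinical, regulator_genes,
                            gene_sets = NULL, response = NULL,
                            expression_unit = "ARBITRARY_LOG",
                            k_range = 2:5, n_runs = 50L,
                            deg_threshold = 0.01, cox_alpha = 0.05,
                            boruta = boruta_config(), ssgsea_alpha = 0.25,
                            seed = 1L, outdir = tempfile("hds_run_")) {
  assert_scalar_number(deg_threshold, "deg_threshold", lower = 1e-12,
                       upper = 1 - 1e-12)
  assert_scalar_number(cox_alpha, "cox_alpha", lower = 1e-12,
                       upper = 1 - 1e-12)
  assert_scalar_number(seed, "seed", integer = TRUE)
  structure(list(expression = expression, clinical = clinical,
                 regulator_genes = regulator_genes, gene_sets = gene_sets,
                 response = response, expression_unit = expression_unit,
                 k_range = k_range, n_runs = as.integer(n_runs),
                 deg_threshold = deg_threshold, cox_alpha = cox_alpha,
                 boruta = boruta, ssgsea_alpha = ssgsea_alpha,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v)
    format(v, digits = 15, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

resolve_inputs <- function(cfg) {
  expr <- cfg$expression
  if (is.character(expr)) expr <- read_expression(expr, cfg$expression_unit)
  if (expr$unit %in% c("FPKM", "TPM")) {
    if (expr$unit == "FPKM") expr <- fpkm_to_tpm(expr)
    expr <- log2p1(expr)
  }
  surv <- cfg$clinical
  if (is.character(surv)) surv <- read_survival(surv)
  panel <- cfg$regulator_genes
  if (is.character(panel) && length(panel) == 1L && file.exists(panel))
    panel <- trimws(readLines(panel))
  panel <- panel[nzchar(panel)]
  missing <- setdiff(panel, rownames(expr$values))
  if (length(missing))
    hds_stop(sprintf("regulator gene(s) missing from expression: %s",
                     paste(missing, collapse = ", ")),
             "hdscore_config_error")
  sets <- cfg$gene_sets
  if (is.character(sets)) sets <- read_gmt(sets)
  list(expr = expr, surv = surv, panel = panel, sets = sets)
}

#' Run the full HDS discovery pipeline
#'
#' Stage order: (1) consensus NMF subtyping of the samples on the regulator
#' panel; (2) moderated-F DEG screen of all non-panel genes between the
#' subtypes at the adjusted-p threshold; (3) univariate Cox screen of the
#' DEGs; (4) Boruta reduction of the prognostic genes against the subtype
#' labels; (5) A/B partition of the confirmed genes by hazard-ratio sign and
#' HDS fitting/scoring; (6) KM + log-rank of high vs low HDS; optional
#' signature correlation (ssGSEA) and immunotherapy response evaluation.
#' Each stage's gene universe is the previous stage's survivors. The whole
#' run is a deterministic function of the configuration.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report`; see [validate_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  inp <- resolve_inputs(config)
  ali <- align_samples(inp$expr, inp$surv)
  expr <- ali$expr; surv <- ali$surv
  if (ncol(expr$values) < 20L)
    hds_stop("fewer than 20 samples shared between expression and clinical data",
             "hdscore_config_error")
  log_path <- file.path(config$outdir, "run.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  logf("hdscore pipeline | seed %d | %d genes x %d samples",
       config$seed, nrow(expr$values), ncol(expr$values))
  stages <- list()
  stage <- function(name, params, n_in, n_out, files) {
    logf("[%s] in=%d out=%d %s", name, n_in, n_out,
         paste(names(params), unlist(params), sep = "=", collapse = " "))
    list(name = name, params = params, n_in = n_in, n_out = n_out,
         files = files)
  }

  ## 1. subtype discovery on the regulator panel
  cons <- consensus_cluster(expr$values[inp$panel, , drop = FALSE],
                            k_range = config$k_range,
                            n_runs = config$n_runs, seed = config$seed,
                            min_cluster_size = 5L)
  labels <- cons$labels
  f_lab <- write_tsv(data.frame(sample = colnames(expr$values),
                                cluster = labels),
                     file.path(config$outdir, "subtypes.tsv"))
  f_met <- write_tsv(data.frame(k = cons$k_range,
                                cophenetic = cons$cophenetic,
                                silhouette = cons$silhouette,
                                error = cons$error),
                     file.path(config$outdir, "subtype_metrics.tsv"))
  stages$subtype <- stage("subtype",
                          list(k = cons$chosen_k, n_runs = config$n_runs,
                               seed = config$seed),
                          length(inp$panel), cons$chosen_k, c(f_lab, f_met))

  ## 2. DEG screen on the non-panel genes
  universe <- setdiff(rownames(expr$values), inp$panel)
  deg <- moderated_anova(expr$values[universe, , drop = FALSE], labels,
                         threshold = config$deg_threshold)
  deg_genes <- deg$gene[deg$significant]
  f_deg <- write_tsv(deg, file.path(config$outdir, "deg.tsv"))
  stages$deg <- stage("deg", list(threshold = config$deg_threshold),
                      length(universe), length(deg_genes), f_deg)
  if (length(deg_genes) == 0L)
    hds_stop(sprintf("no genes pass the DEG stage at adjusted p < %g",
                     config$deg_threshold), "hdscore_pipeline_error")

  ## 3. univariate Cox prognostic screen
  scr <- screen_prognostic(expr$values[deg_genes, , drop = FALSE], surv,
                           alpha = config$cox_alpha)
  prog_genes <- scr$gene[scr$class != "none"]
  f_scr <- write_tsv(scr, file.path(config$outdir, "cox_screen.tsv"))
  stages$coxscreen <- stage("coxscreen", list(alpha = config$cox_alpha),
                            length(deg_genes), length(prog_genes), f_scr)
  if (length(prog_genes) < 4L)
    hds_stop(sprintf("fewer than 4 genes pass the Cox screen at p < %g",
                     config$cox_alpha), "hdscore_pipeline_error")

  ## 4. Boruta reduction against the subtype labels
  bor <- boruta_select(t(expr$values[prog_genes, , drop = FALSE]),
                       factor(labels), config$boruta)
  sel_genes <- boruta_confirmed(bor)
  f_bor <- write_tsv(data.frame(gene = names(bor$status),
                                status = bor$status,
                                resolved = bor$resolved,
                                hits = bor$hits,
                                iterations = bor$iterations,
                                median_importance = bor$median_importance),
                     file.path(config$outdir, "boruta.tsv"))
  stages$boruta <- stage("boruta",
                         list(alpha = bor$config$alpha,
                              n_trees = bor$config$n_trees,
                              seed = bor$config$seed),
                         length(prog_genes), length(sel_genes), f_bor)
  if (length(sel_genes) < 4L)
    hds_stop("fewer than 4 Boruta-confirmed genes", "hdscore_pipeline_error")

  ## 5. A/B partition and HDS
  cls <- scr$class[match(sel_genes, scr$gene)]
  setA <- sel_genes[cls == "A"]; setB <- sel_genes[cls == "B"]
  if (length(setA) < 2L || length(setB) < 2L)
    hds_stop("need at least 2 genes in each of set A and set B",
             "hdscore_pipeline_error")
  model <- fit_hds(expr, setA, setB)
  scores <- score_hds(model, expr)
  f_model <- write_hds_model(model, file.path(config$outdir, "hds_model.json"))
  f_scores <- write_tsv(scores, file.path(config$outdir, "hds_scores.tsv"))
  stages$hds <- stage("hds", list(nA = length(setA), nB = length(setB)),
                      length(sel_genes), length(setA) + length(setB),
                      c(f_model, f_scores))

  ## 6. survival contrast of high vs low HDS
  lr <- logrank_test(surv, scores$group)
  km <- km_estimate(surv, scores$group)
  km_df <- do.call(rbind, lapply(names(km), function(g)
    cbind(group = g, km[[g]])))
  f_km <- write_tsv(km_df, file.path(config$outdir, "km_curves.tsv"))
  f_lr <- write_tsv(data.frame(chisq = lr$chisq, df = lr$df, p = lr$p),
                    file.path(config$outdir, "logrank.tsv"))
  stages$survdiff <- stage("survdiff", list(p = signif(lr$p, 6)),
                           nrow(surv), 2L, c(f_km, f_lr))

  ## optional: signature correlation
  corr <- NULL
  if (!is.null(inp$sets)) {
    enr <- score_collection(expr, inp$sets, alpha = config$ssgsea_alpha)
    corr <- correlate_with_signatures(scores$hds, enr)
    f_enr <- write_tsv(data.frame(signature = rownames(enr), enr,
                                  check.names = FALSE),
                       file.path(config$outdir, "enrichment.tsv"))
    f_cor <- write_tsv(corr, file.path(config$outdir,
                                       "signature_correlation.tsv"))
    stages$ssgsea <- stage("ssgsea", list(alpha = config$ssgsea_alpha),
                           length(inp$sets), nrow(corr), c(f_enr, f_cor))
  }

  ## optional: response evaluation
  resp_eval <- NULL
  if (!is.null(config$response)) {
    rc <- config$response
    rc$hds <- scores$hds[match(rc$sample, scores$sample)]
    rc <- rc[!is.na(rc$hds), , drop = FALSE]
    fit <- fit_logistic(as.matrix(rc[, c("hds", "cps", "msi")]),
                        rc$response)
    roc_hds <- roc_auc(rc$hds, rc$response)
    roc_comb <- roc_auc(predict_logistic(
      fit, as.matrix(rc[, c("hds", "cps", "msi")])), rc$response)
    resp_eval <- list(fit = fit, auc_hds = roc_hds$auc,
                      auc_combined = roc_comb$auc)
    f_resp <- write_tsv(data.frame(term = names(fit$coef),
                                   coef = fit$coef, se = fit$se, p = fit$p),
                        file.path(config$outdir, "response_model.tsv"))
    stages$respond <- stage("respond",
                            list(auc_hds = signif(roc_hds$auc, 6),
                                 auc_combined = signif(roc_comb$auc, 6)),
                            nrow(rc), length(fit$coef), f_resp)
  }

  report <- structure(list(
    stages = stages, seed = config$seed, outdir = config$outdir,
    counts = list(deg = length(deg_genes), prognostic = length(prog_genes),
                  selected = length(sel_genes),
                  nA = length(setA), nB = length(setB)),
    setA = setA, setB = setB, model = model, scores = scores,
    subtypes = labels, consensus = cons, logrank = lr,
    signature_correlation = corr, response = resp_eval,
    wall_time = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  ), class = "pipeline_report")
  report
}

#' Validate internal consistency of a pipeline report
#'
#' Re-checks that every declared output file exists, that stage gene counts
#' are monotone (DEG >= prognostic >= selected = |A| + |B|), and that the
#' master seed was recorded.
#'
#' @param report a [run_pipeline()] result.
#' @return character vector of violations (empty when the report is sound).
#' @export
validate_report <- function(report) {
  v <- character(0)
  files <- unlist(lapply(report$stages, `[[`, "files"))
  for (f in files)
    if (!file.exists(f)) v <- c(v, sprintf("missing file: %s", f))
  cn <- report$counts
  if (cn$nA + cn$nB != cn$selected)
    v <- c(v, sprintf("partition violation: |A| + |B| = %d != selected = %d",
                      cn$nA + cn$nB, cn$selected))
  if (!(cn$deg >= cn$prognostic && cn$prognostic >= cn$selected))
    v <- c(v, "stage-count monotonicity violated")
  if (is.null(report$seed) || !is.finite(report$seed))
    v <- c(v, "master seed not recorded")
  v
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> seed %d | DEG %d -> prognostic %d -> selected %d (A %d / B %d)\n",
              x$seed, x$counts$deg, x$counts$prognostic, x$counts$selected,
              x$counts$nA, x$counts$nB))
  cat(sprintf("  log-rank high vs low HDS: chisq %.3f, p %.3g\n",
              x$logrank$chisq, x$logrank$p))
  invisible(x)
}
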