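# Key-value configuration files (YAML or JSON) for the generators and the
# pipeline, so runs are reproducible from a single text file plus a seed.

read_config_list <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Read a cohort configuration from a YAML/JSON file
#'
#' Keys mirror the arguments of [cohort_config()]; absent keys keep their
#' defaults, unknown keys are an error.
#'
#' @param path YAML (default) or JSON file.
#' @return a [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  vals <- read_config_list(path)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    hds_stop(sprintf("unknown cohort config key(s): %s",
                     paste(bad, collapse = ", ")),
             "hdscore_config_error")
  do.call(cohort_config, vals)
}

#' Read a pipeline configuration from a YAML/JSON file
#'
#' Keys mirror [pipeline_config()]; `boruta` may be a nested map with
#' [boruta_config()] keys. File-path values are interpreted relative to the
#' config file's directory.
#'
#' @param path YAML (default) or JSON file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- read_config_list(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    hds_stop(sprintf("unknown pipeline config key(s): %s",
                     paste(bad, collapse = ", ")),
             "hdscore_config_error")
  base <- dirname(normalizePath(path))
  rel <- function(p)
    if (is.character(p) && length(p) == 1L && !file.exists(p) &&
        file.exists(file.path(base, p))) file.path(base, p) else p
  for (f in c("expression", "clinical", "regulator_genes", "gene_sets"))
    if (!is.null(vals[[f]])) vals[[f]] <- rel(vals[[f]])
  if (!is.null(vals$boruta)) vals$boruta <- do.call(boruta_config, vals$boruta)
  if (!is.null(vals$k_range)) vals$k_range <- as.integer(vals$k_range)
  do.call(pipeline_config, vals)
}
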