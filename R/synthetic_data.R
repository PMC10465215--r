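# Synthetic cohorts with known ground truth: three regulator-driven latent
# subtypes, protective/risk transcriptional programs tied to proportional-
# hazards survival, immune-signature structure, and a logistic response model.
#
# Expression is simulated directly on the log2 scale with Gaussian noise (the
# pipeline consumes normalized arrays, not counts). Subtype 1 is the
# poor-prognosis subtype, subtype 3 the good-prognosis one, mirroring the
# worst-to-best ordering of regulator-defined clusters in gastric cancer.

#' Configuration of a synthetic gastric-cancer-like cohort
#'
#' @param n_samples number of samples.
#' @param n_regulator_genes size of the regulator panel (default 18, the
#'   number of human HDAC/sirtuin genes).
#' @param n_protective_genes,n_risk_genes,n_noise_genes downstream program
#'   and background gene counts.
#' @param cluster_probs length-3 probability vector of latent subtype
#'   membership (must sum to 1).
#' @param cluster_effect log2-expression shift applied to the genes elevated
#'   in a subtype (unitless, log2 scale).
#' @param noise_sd Gaussian noise s.d. on the log2 scale.
#' @param beta_protective log-hazard per unit (z-scaled) protective program
#'   score; must be <= 0.
#' @param beta_risk log-hazard per unit risk program score; must be >= 0.
#' @param baseline_scale,baseline_shape Weibull baseline parameters (time
#'   units arbitrary; months by convention).
#' @param censor_rate target fraction of censored samples (independent
#'   uniform censoring on `[0, T_max]`, `T_max` calibrated by bisection).
#' @param seed integer seed; the cohort is a deterministic function of the
#'   full configuration.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 300L,
                          n_regulator_genes = 18L,
                          n_protective_genes = 60L,
                          n_risk_genes = 50L,
                          n_noise_genes = 400L,
                          cluster_probs = c(1, 1, 1) / 3,
                          cluster_effect = 2,
                          noise_sd = 0.5,
                          beta_protective = -0.7,
                          beta_risk = 0.7,
                          baseline_scale = 60,
                          baseline_shape = 1.2,
                          censor_rate = 0.3,
                          seed = 1L) {
  assert_scalar_number(n_samples, "n_samples", lower = 2, integer = TRUE)
  assert_scalar_number(n_regulator_genes, "n_regulator_genes", lower = 3,
                       integer = TRUE)
  assert_scalar_number(n_protective_genes, "n_protective_genes", lower = 1,
                       integer = TRUE)
  assert_scalar_number(n_risk_genes, "n_risk_genes", lower = 1, integer = TRUE)
  assert_scalar_number(n_noise_genes, "n_noise_genes", lower = 1,
                       integer = TRUE)
  if (length(cluster_probs) != 3L || any(!is.finite(cluster_probs)) ||
      any(cluster_probs < 0) || abs(sum(cluster_probs) - 1) > 1e-12)
    hds_stop("cluster_probs must be 3 non-negative values summing to 1 (within 1e-12)",
             "hdscore_config_error")
  assert_scalar_number(cluster_effect, "cluster_effect")
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(beta_protective, "beta_protective", upper = 0)
  assert_scalar_number(beta_risk, "beta_risk", lower = 0)
  assert_scalar_number(baseline_scale, "baseline_scale", lower = 1e-12)
  assert_scalar_number(baseline_shape, "baseline_shape", lower = 1e-12)
  assert_scalar_number(censor_rate, "censor_rate", lower = 0, upper = 0.95)
  assert_scalar_number(seed, "seed", integer = TRUE)
  structure(list(
    n_samples = as.integer(n_samples),
    n_regulator_genes = as.integer(n_regulator_genes),
    n_protective_genes = as.integer(n_protective_genes),
    n_risk_genes = as.integer(n_risk_genes),
    n_noise_genes = as.integer(n_noise_genes),
    cluster_probs = as.numeric(cluster_probs),
    cluster_effect = cluster_effect, noise_sd = noise_sd,
    beta_protective = beta_protective, beta_risk = beta_risk,
    baseline_scale = baseline_scale, baseline_shape = baseline_shape,
    censor_rate = censor_rate, seed = as.integer(seed)
  ), class = "cohort_config")
}

# bisect T_max of a U(0, T_max) censoring time so that the expected censoring
# fraction, mean_i P(C_i < T_i) = mean_i min(T_i / T_max, 1), hits the target
calibrate_censor_tmax <- function(times, target) {
  f <- function(tmax) mean(pmin(times / tmax, 1)) - target
  lo <- max(times)            # f(lo) <= mean(1) boundary; f decreasing in tmax
  while (f(lo) < 0) lo <- lo / 2
  hi <- lo
  while (f(hi) > 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) / hi < 1e-12) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic cohort with planted subtype and survival structure
#'
#' Each sample belongs to one of three latent subtypes. The regulator panel
#' is split into three disjoint blocks, each elevated (by `cluster_effect`)
#' in exactly one subtype. Protective-program genes are elevated in the
#' good-prognosis subtype (3), risk genes in the poor-prognosis subtype (1).
#' Survival times are Weibull with log-hazard
#' `beta_protective * zP + beta_risk * zR`, where zP / zR are the z-scaled
#' per-sample means of the protective / risk genes; censoring is independent
#' uniform with its upper bound calibrated to `censor_rate`.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `expression`
#'   (an [expression_matrix()], unit ARBITRARY_LOG), `survival`
#'   (a [survival_table()]), and `truth` (latent cluster labels, true program
#'   scores, planted gene lists).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  cluster <- sample.int(3L, n, replace = TRUE, prob = cf$cluster_probs)

  reg_genes <- sprintf("REG%02d", seq_len(cf$n_regulator_genes))
  pro_genes <- sprintf("PRO%03d", seq_len(cf$n_protective_genes))
  rsk_genes <- sprintf("RSK%03d", seq_len(cf$n_risk_genes))
  noi_genes <- sprintf("NSE%04d", seq_len(cf$n_noise_genes))
  genes <- c(reg_genes, pro_genes, rsk_genes, noi_genes)

  baseline <- 5  # log2 units, typical moderate expression
  mu <- matrix(baseline, nrow = length(genes), ncol = n,
               dimnames = list(genes, samples))
  # three disjoint regulator blocks, block b elevated in subtype b
  block <- sort(rep(1:3, length.out = cf$n_regulator_genes))
  for (b in 1:3)
    mu[reg_genes[block == b], cluster == b] <-
      mu[reg_genes[block == b], cluster == b] + cf$cluster_effect
  mu[pro_genes, cluster == 3L] <- mu[pro_genes, cluster == 3L] + cf$cluster_effect
  mu[rsk_genes, cluster == 1L] <- mu[rsk_genes, cluster == 1L] + cf$cluster_effect

  expr <- mu + matrix(stats::rnorm(length(mu), sd = cf$noise_sd),
                      nrow = nrow(mu))
  dimnames(expr) <- dimnames(mu)

  zP <- as.numeric(scale(colMeans(expr[pro_genes, , drop = FALSE])))
  zR <- as.numeric(scale(colMeans(expr[rsk_genes, , drop = FALSE])))
  eta <- cf$beta_protective * zP + cf$beta_risk * zR
  # Weibull PH: S(t|x) = exp(-(t/scale)^shape * exp(eta))
  u <- stats::runif(n)
  t_true <- cf$baseline_scale * (-log(u) / exp(eta))^(1 / cf$baseline_shape)
  if (cf$censor_rate > 0) {
    tmax <- calibrate_censor_tmax(t_true, cf$censor_rate)
    cens <- stats::runif(n, 0, tmax)
    time <- pmin(t_true, cens)
    event <- as.integer(t_true <= cens)
  } else {
    time <- t_true
    event <- rep(1L, n)
  }
  time <- pmax(time, 1e-8)

  structure(list(
    expression = expression_matrix(expr, "ARBITRARY_LOG"),
    survival = survival_table(data.frame(
      sample = samples, time = time, event = event,
      stringsAsFactors = FALSE)),
    truth = list(cluster = cluster,
                 protective_score = zP, risk_score = zR,
                 regulator_genes = reg_genes,
                 protective_genes = pro_genes,
                 risk_genes = rsk_genes,
                 noise_genes = noi_genes),
    config = cf
  ), class = "synthetic_cohort")
}

#' Plant immune-cell marker signatures into a synthetic cohort
#'
#' For each of `n_cell_types` synthetic cell types, a disjoint marker gene
#' set is drawn from the cohort's noise genes (never from the regulator
#' panel) and each marker's expression is shifted by `shift * abundance` per
#' sample. Cell type 1's abundance is constructed to correlate positively
#' with the protective program, cell type 2's negatively; the rest are
#' independent standard normals.
#'
#' @param cohort a [generate_cohort()] result.
#' @param n_cell_types number of synthetic cell types (K >= 1).
#' @param n_markers markers per cell type.
#' @param shift log2 expression shift per unit abundance.
#' @param seed integer seed.
#' @return list of class `signature_collection_sim`: `expression` (the
#'   cohort expression with marker shifts applied), `sets`
#'   (a [gene_set_collection()]), `abundance` (cell type x sample matrix).
#' @export
generate_signature_collection <- function(cohort, n_cell_types = 5L,
                                          n_markers = 15L, shift = 1.5,
                                          seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  assert_scalar_number(n_cell_types, "n_cell_types", lower = 1, integer = TRUE)
  assert_scalar_number(n_markers, "n_markers", lower = 2, integer = TRUE)
  assert_scalar_number(shift, "shift")
  pool <- cohort$truth$noise_genes
  if (length(pool) < n_cell_types * n_markers)
    hds_stop("not enough noise genes to host the marker sets",
             "hdscore_config_error")
  set.seed(seed)
  picked <- sample(pool, n_cell_types * n_markers)
  sets <- split(picked, rep(seq_len(n_cell_types), each = n_markers))
  names(sets) <- sprintf("CellType%02d", seq_len(n_cell_types))

  n <- ncol(cohort$expression$values)
  zP <- cohort$truth$protective_score
  abundance <- matrix(stats::rnorm(n_cell_types * n), nrow = n_cell_types,
                      dimnames = list(names(sets),
                                      colnames(cohort$expression$values)))
  # correlate planted abundances with the protective program (rho ~ 0.8)
  if (n_cell_types >= 1)
    abundance[1L, ] <- as.numeric(scale(0.8 * zP + 0.6 * stats::rnorm(n)))
  if (n_cell_types >= 2)
    abundance[2L, ] <- as.numeric(scale(-0.8 * zP + 0.6 * stats::rnorm(n)))

  expr <- cohort$expression$values
  for (k in seq_len(n_cell_types))
    expr[sets[[k]], ] <- expr[sets[[k]], ] +
      shift * matrix(abundance[k, ], nrow = n_markers, ncol = n, byrow = TRUE)

  list(expression = expression_matrix(expr, "ARBITRARY_LOG"),
       sets = gene_set_collection(sets),
       abundance = abundance)
}

#' Generate a pembrolizumab-like immunotherapy response cohort
#'
#' Per patient: a unit-normal latent score (HDS), a non-negative ordinal
#' PD-L1 combined positive score (CPS), binary MSI-H status, and a binary
#' RECIST response (CR/PR = 1) drawn from
#' `Bernoulli(plogis(intercept + coef_hds*hds + coef_cps*cps + coef_msi*msi))`.
#'
#' @param n number of patients (>= 10).
#' @param coef_hds,coef_cps,coef_msi,intercept logistic model coefficients.
#' @param seed integer seed.
#' @return data.frame of class `response_cohort` with columns `hds`, `cps`,
#'   `msi`, `response`, and the latent response probability `prob`.
#' @export
generate_response_cohort <- function(n, coef_hds = 1, coef_cps = 0.1,
                                     coef_msi = 1, intercept = -1,
                                     seed = 1L) {
  assert_scalar_number(n, "n", lower = 10, integer = TRUE)
  for (v in c(coef_hds, coef_cps, coef_msi, intercept))
    if (!is.finite(v))
      hds_stop("coefficients must be finite", "hdscore_config_error")
  set.seed(seed)
  hds <- stats::rnorm(n)
  cps <- floor(stats::rexp(n, rate = 1 / 8))  # right-skewed ordinal, mean ~8
  cps <- pmin(cps, 100)
  msi <- stats::rbinom(n, 1L, 0.25)
  prob <- stats::plogis(intercept + coef_hds * hds + coef_cps * cps +
                          coef_msi * msi)
  response <- stats::rbinom(n, 1L, prob)
  structure(data.frame(hds = hds, cps = cps, msi = msi,
                       response = response, prob = prob),
            class = c("response_cohort", "data.frame"))
}
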