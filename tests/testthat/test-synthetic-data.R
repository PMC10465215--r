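test_that("cohort generation is deterministic and respects the config", {
  cfg <- cohort_config(n_samples = 80, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$survival$time, b$survival$time)
  expect_identical(a$truth$cluster, b$truth$cluster)
  # expression columns align with survival ids; truth partitions non-panel genes
  expect_identical(colnames(a$expression$values), a$survival$sample)
  non_panel <- setdiff(rownames(a$expression$values), a$truth$regulator_genes)
  expect_setequal(non_panel, c(a$truth$protective_genes, a$truth$risk_genes,
                               a$truth$noise_genes))
})

test_that("zero noise collapses subtype regulator profiles to identical vectors", {
  coh <- generate_cohort(cohort_config(n_samples = 40, noise_sd = 0,
                                       seed = 3))
  reg <- coh$expression$values[coh$truth$regulator_genes, ]
  for (k in 1:3) {
    cols <- reg[, coh$truth$cluster == k, drop = FALSE]
    expect_true(all(cols == cols[, 1]))
  }
})

test_that("config validation rejects out-of-range values", {
  expect_error(cohort_config(cluster_probs = c(0.5, 0.5, 0.1)), "summing to 1")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(beta_protective = 0.2), "beta_protective")
  expect_error(cohort_config(censor_rate = 2), "censor_rate")
})

test_that("censoring calibration lands within 5 points of the target", {
  for (target in c(0.2, 0.4)) {
    coh <- generate_cohort(cohort_config(n_samples = 1200,
                                         censor_rate = target, seed = 7))
    expect_lt(abs(mean(coh$survival$event == 0) - target), 0.05)
  }
})

test_that("planted log-hazard is recovered by the Cox module as n grows", {
  for (n in c(500, 2000)) {
    coh <- generate_cohort(cohort_config(
      n_samples = n, beta_risk = log(2), beta_protective = 0,
      censor_rate = 0.3, seed = 4))
    fit <- cox_fit(matrix(coh$truth$risk_score, ncol = 1), coh$survival)
    expect_gt(fit$hr, 1.8 - (n == 500) * 0.15)  # looser band at small n
    expect_lt(fit$hr, 2.2 + (n == 500) * 0.15)
  }
})

test_that("signature marker sets are disjoint from the panel and recover planted abundance", {
  coh <- fixture("sig_cohort", function()
    generate_cohort(cohort_config(n_samples = 200, noise_sd = 0.5, seed = 5)))
  sim <- generate_signature_collection(coh, n_cell_types = 4, shift = 1.5,
                                       seed = 2)
  all_markers <- unlist(sim$sets)
  expect_length(intersect(all_markers, coh$truth$regulator_genes), 0)
  expect_false(anyDuplicated(all_markers) > 0)  # marker sets are disjoint
  enr <- score_collection(sim$expression, sim$sets)
  for (k in seq_along(sim$sets)) {
    rho <- cor(enr[k, ], sim$abundance[k, ], method = "spearman")
    expect_gte(rho, 0.8)
  }
})

test_that("zero marker shift gives no score-abundance association", {
  pvals <- vapply(1:20, function(s) {
    coh <- generate_cohort(cohort_config(n_samples = 60,
                                         n_noise_genes = 120, seed = s))
    sim <- generate_signature_collection(coh, n_cell_types = 3,
                                         n_markers = 8, shift = 0, seed = s)
    enr <- score_collection(sim$expression, sim$sets["CellType03"])
    cor.test(enr[1, ], sim$abundance[3, ], method = "spearman",
             exact = FALSE)$p.value
  }, 0)
  # under the null the correlation should rarely be significant
  expect_lte(mean(pvals < 0.05), 0.2)
})

test_that("response cohort follows its logistic generative model", {
  # null model: response rate near 0.5
  null_rc <- generate_response_cohort(1000, coef_hds = 0, coef_cps = 0,
                                      coef_msi = 0, intercept = 0, seed = 4)
  ci <- binom.test(sum(null_rc$response), 1000, 0.5)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
  # strong score separates responders
  strong <- generate_response_cohort(500, coef_hds = 5, coef_cps = 0,
                                     coef_msi = 0, intercept = 0, seed = 2)
  expect_gte(roc_auc(strong$hds, strong$response)$auc, 0.95)
  # parameter recovery at n = 5000
  rc <- generate_response_cohort(5000, coef_hds = 2, coef_cps = 0.1,
                                 coef_msi = 1, intercept = -1, seed = 8)
  fit <- fit_logistic(as.matrix(rc[, c("hds", "cps", "msi")]), rc$response)
  planted <- c(-1, 2, 0.1, 1)
  expect_true(all(abs(fit$coef - planted) <= pmax(0.15 * abs(planted), 0.1)))
  expect_identical(rc$msi %in% c(0L, 1L), rep(TRUE, 5000))
  expect_true(all(rc$cps >= 0))
})
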