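# Shared fixtures, built in code. Cached per test session so several test
# files can reuse the same synthetic cohorts without regenerating them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

default_cohort <- function() {
  fixture("default_cohort", function() generate_cohort(cohort_config(seed = 1)))
}

# small expression matrix with known content for IO tests
toy_expression <- function() {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  expression_matrix(m, "TPM")
}

# 6-observation survival toys used for Cox / log-rank oracles
toy_surv_separated <- function() {
  survival_table(data.frame(sample = paste0("p", 1:6), time = 1:6, event = 1L))
}

# written-out Breslow partial log-likelihood for 6 distinct event times, all
# events: the independent brute-force oracle used against cox_fit
breslow_loglik_toy <- function(beta, x) {
  eta <- x * beta
  sum(eta) - sum(vapply(1:6, function(i) log(sum(exp(eta[i:6]))), 0))
}
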