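# Shared synthetic cohorts, generated once per test run.

.cohort_cache <- new.env(parent = emptyenv())

# The reference cohort at the study-condition defaults (n = 50,000).
reference_cohort <- function() {
  if (is.null(.cohort_cache$ref)) {
    .cohort_cache$ref <- generate_cohort(example_cohort_spec(50000, seed = 101),
                                         keep_latents = TRUE)
  }
  .cohort_cache$ref
}

# A cohort whose outcome is independent of both exposures (all log-RR 0).
null_effect_spec <- function(n = 50000, seed = 202) {
  cohort_spec(
    n_individuals = n,
    exposures = c(physical = 0.261, emotional = 0.126),
    confounders = list(ses = list(dist = "normal"),
                       dependants = list(dist = "normal")),
    outcomes = list(
      alcohol_abuse = list(intercept = log(0.08),
                           log_rr = c(physical = 0, emotional = 0),
                           confounders = c(ses = 0.1)),
      anxiety = list(intercept = log(0.10),
                     log_rr = c(physical = 0, emotional = 0),
                     confounders = c(ses = 0.1))
    ),
    wage = list(intercept = log(3000), reductions = c(physical = 0, emotional = 0),
                confounders = c(ses = 0.3), sigma = 0.6),
    selection = list(intercept = 0.3,
                     confounders = c(ses = 0.3, dependants = -0.4),
                     rho = 0),
    seed = seed
  )
}

null_cohort <- function() {
  if (is.null(.cohort_cache$null)) {
    .cohort_cache$null <- generate_cohort(null_effect_spec())
  }
  .cohort_cache$null
}

# Monte-Carlo standard error of a crude risk ratio from stratum counts
# (delta method on the log scale).
crude_rr_se <- function(events1, n1, events0, n0, rr) {
  rr * sqrt(1 / events1 - 1 / n1 + 1 / events0 - 1 / n0)
}
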