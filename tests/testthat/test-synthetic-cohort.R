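test_that("spec validation rejects impossible parameters, naming the offender", {
  base <- function(...) {
    args <- modifyList(list(
      n_individuals = 100,
      exposures = c(physical = 0.3),
      confounders = list(ses = list(dist = "normal")),
      outcomes = list(y = list(intercept = log(0.1),
                               log_rr = c(physical = log(2)))),
      seed = 1
    ), list(...))
    do.call(cohort_spec, args)
  }
  expect_s3_class(base(), "cohort_spec")
  expect_error(base(exposures = c(physical = 1.2)), "physical")
  expect_error(base(n_individuals = 0), "positive integer")
  # intercept + log-RR implies risk > 1 in the exposed stratum
  expect_error(base(outcomes = list(y = list(intercept = log(0.9),
                                             log_rr = c(physical = log(2))))),
               "worst-case implied risk")
  # rho on the boundary is rejected
  expect_error(
    cohort_spec(n_individuals = 10, exposures = c(physical = 0.3),
                outcomes = list(),
                wage = list(intercept = 8, reductions = c(physical = 0.1),
                            sigma = 0.5),
                selection = list(intercept = 0, rho = 1), seed = 1),
    "rho")
  # unknown covariate in an outcome model
  expect_error(base(outcomes = list(y = list(intercept = log(0.1),
                                             log_rr = c(physical = 0),
                                             confounders = c(nope = 1)))),
               "unknown confounder")
})

test_that("zero prevalence yields identically zero exposure columns", {
  spec <- cohort_spec(
    n_individuals = 300,
    exposures = c(physical = 0, emotional = 0),
    outcomes = list(y = list(intercept = log(0.2),
                             log_rr = c(physical = log(2)))),
    seed = 4
  )
  co <- generate_cohort(spec)
  expect_identical(unique(co$physical), 0L)
  expect_identical(unique(co$emotional), 0L)
})

test_that("generation is bit-identical for the same spec and seed", {
  spec <- example_cohort_spec(2000, seed = 42)
  a <- generate_cohort(spec, keep_latents = TRUE)
  b <- generate_cohort(spec, keep_latents = TRUE)
  expect_identical(a, b)
  c <- generate_cohort(example_cohort_spec(2000, seed = 43))
  expect_false(identical(a$physical, c$physical))
})

test_that("empirical prevalences and participation match the spec within 4 SE at n = 50,000", {
  co <- reference_cohort()
  spec <- attr(co, "cohort_spec")
  s <- empirical_summary(co)
  n <- nrow(co)
  for (e in names(spec$exposures)) {
    p <- spec$exposures[[e]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(s$prevalence[[e]] - p), 4 * se)
  }
  # participation rate implied by the probit model: P(lp + e > 0) averaged
  lp <- spec$selection$intercept +
    0.5 * spec$selection$confounders[["female"]]  # E[female] = 0.5, others 0
  # linear predictor is lp + b_ses*ses + b_dep*dep with N(0,1) covariates
  sd_lp <- sqrt(1 + spec$selection$confounders[["ses"]]^2 +
                  spec$selection$confounders[["dependants"]]^2)
  p_part <- pnorm(lp / sd_lp)
  expect_lt(abs(s$participation_rate - p_part),
            4 * sqrt(p_part * (1 - p_part) / n) + 0.01)
})

test_that("latent residual correlation recovers rho", {
  co <- reference_cohort()
  rho <- attr(co, "cohort_spec")$selection$rho
  r <- cor(co$.participation_resid, co$.wage_resid)
  expect_lt(abs(r - rho), 4 / sqrt(nrow(co)))
})

test_that("risk exceeding 1 is rejected at generation, never truncated", {
  spec <- cohort_spec(
    n_individuals = 5000,
    exposures = c(physical = 0.3),
    confounders = list(ses = list(dist = "normal")),
    outcomes = list(y = list(intercept = log(0.4) - 0.9,
                             log_rr = c(physical = 0),
                             confounders = c(ses = 0.4))),
    seed = 1
  )
  spec$outcomes$y$confounders <- c(ses = 5)  # mutate past construction checks
  expect_error(generate_cohort(spec), "risk")
  expect_error(generate_cohort(spec), "y")  # names the offending outcome
})

test_that("crude RRs from empirical_summary match construction", {
  # 4-row handmade cohort with risk 1/2 in both strata
  tiny <- structure(tibble::tibble(x = c(1, 1, 0, 0), y = c(1, 0, 1, 0)),
                    class = c("cohort_table", class(tibble::tibble())))
  s <- empirical_summary(tiny, exposures = "x", outcomes = "y")
  expect_equal(s$risks$crude_rr, 1.0)

  # null effect at large n: crude RR within sampling error of 1
  co <- null_cohort()
  s <- empirical_summary(co)
  for (i in seq_len(nrow(s$risks))) {
    r <- s$risks[i, ]
    n1 <- sum(co[[r$exposure]] == 1); n0 <- sum(co[[r$exposure]] == 0)
    se <- crude_rr_se(r$risk_exposed * n1, n1, r$risk_unexposed * n0, n0,
                      r$crude_rr)
    expect_lt(abs(r$crude_rr - 1), 3 * se)
  }

  # known truth on the published physical-violence -> alcohol scale (1.55):
  # exposures independent of the confounder, so the marginal RR is exp(b)
  co <- reference_cohort()
  r <- empirical_summary(co)$risks
  r <- r[r$exposure == "physical" & r$outcome == "alcohol_abuse", ]
  n1 <- sum(co$physical == 1); n0 <- sum(co$physical == 0)
  se <- crude_rr_se(r$risk_exposed * n1, n1, r$risk_unexposed * n0, n0,
                    r$crude_rr)
  expect_lt(abs(r$crude_rr - 1.55), 3 * se)
})

test_that("empty cohorts and absent strata are errors / NA, not zeros", {
  empty <- tibble::tibble(x = integer(), y = integer())
  expect_error(empirical_summary(empty, exposures = "x", outcomes = "y"),
               "empty")
  one_sided <- tibble::tibble(x = c(1, 1), y = c(1, 0))
  s <- empirical_summary(one_sided, exposures = "x", outcomes = "y")
  expect_true(is.na(s$risks$risk_unexposed))
  expect_true(is.na(s$risks$crude_rr))
})

test_that("cohort CSV round-trips with empty-field wages; YAML specs load", {
  co <- generate_cohort(example_cohort_spec(200, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  raw <- readLines(path)
  expect_true(any(grepl(",$", raw) | grepl(",,", raw)))  # empty wage fields
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co), ignore_attr = TRUE)
  expect_identical(is.na(back$wage), back$participation == 0L)

  # wage present without participation is rejected on read
  bad <- co
  bad$wage[which(bad$participation == 0)[1]] <- 123
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(bad, path2)
  expect_error(read_cohort(path2), "consistency")

  spec_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_individuals: 50",
    "seed: 3",
    "exposures: {physical: 0.3}",
    "confounders:",
    "  ses: {dist: normal}",
    "outcomes:",
    "  anxiety:",
    "    intercept: -2.0",
    "    log_rr: {physical: 0.5}",
    "    confounders: {ses: 0.1}"
  ), spec_path)
  spec <- read_cohort_spec(spec_path)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(spec$exposures, c(physical = 0.3))
  expect_equal(spec$outcomes$anxiety$log_rr, c(physical = 0.5))
  expect_silent(generate_cohort(spec))
})
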