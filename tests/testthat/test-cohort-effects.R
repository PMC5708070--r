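test_that("a saturated 2x2 fit returns the closed-form crude risk ratio exactly", {
  # 100 exposed with 20 events, 100 unexposed with 10 events -> RR = 2
  tab <- tibble::tibble(
    x = rep(c(1, 0), each = 100),
    y = c(rep(c(1, 0), c(20, 80)), rep(c(1, 0), c(10, 90)))
  )
  est <- estimate_rr(tab, "x", "y")
  expect_equal(est$rr, 2.0, tolerance = 1e-10)
  expect_equal(est$method, "log-binomial")
  expect_equal(est$n, 200)

  # and generally: random 2x2 tables match risk(exposed)/risk(unexposed)
  set.seed(31)
  for (i in 1:5) {
    n1 <- sample(50:200, 1); n0 <- sample(50:200, 1)
    e1 <- sample(seq_len(n1 - 1), 1); e0 <- sample(seq_len(n0 - 1), 1)
    tab <- tibble::tibble(x = rep(c(1, 0), c(n1, n0)),
                          y = c(rep(c(1, 0), c(e1, n1 - e1)),
                                rep(c(1, 0), c(e0, n0 - e0))))
    expect_equal(estimate_rr(tab, "x", "y")$rr, (e1 / n1) / (e0 / n0),
                 tolerance = 1e-8)
  }
})

test_that("null and non-null relative risks are recovered within 3 SE", {
  co <- null_cohort()
  est <- estimate_rr(co, "physical", "alcohol_abuse", adjust_for = "ses")
  expect_lt(abs(log(est$rr)), 3 * est$log_rr_se)

  co <- reference_cohort()
  est <- estimate_rr(co, "physical", "alcohol_abuse",
                     adjust_for = c("ses", "female"))
  expect_lt(abs(log(est$rr) - log(1.55)), 3 * est$log_rr_se)
})

test_that("degenerate inputs produce instructive errors", {
  tab <- tibble::tibble(x = rep(c(1, 0), each = 10),
                        y = c(rep(0, 10), rep(c(1, 0), c(3, 7))))
  expect_error(estimate_rr(tab, "x", "y"), "continuity")
  expect_error(estimate_rr(tab, "nope", "y"), "missing column")
  expect_error(estimate_rr(tibble::tibble(x = rep(1, 5), y = rep(1, 5)),
                           "x", "y"), "non-empty")
})

test_that("inverse Mills ratio matches its analytic values", {
  expect_equal(inverse_mills(0), sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(inverse_mills(0), 0.7978846, tolerance = 1e-7)
  # lambda(x) = dnorm/pnorm by definition, monotone decreasing
  x <- seq(-3, 3, by = 0.5)
  expect_equal(inverse_mills(x), dnorm(x) / pnorm(x))
  expect_true(all(diff(inverse_mills(x)) < 0))
})

test_that("stage 2 with the Mills column forced to zero is exactly OLS", {
  co <- reference_cohort()
  dat <- as.data.frame(co[co$participation == 1, ])
  h <- vacburden:::heckman_stage2(dat, "physical + female + ses",
                                  mills = rep(0, nrow(dat)))
  ols <- lm(log(wage) ~ physical + female + ses, data = dat)
  expect_equal(coef(h)[names(coef(ols))], coef(ols), tolerance = 1e-12)
})

test_that("with rho = 0 the Mills coefficient vanishes and OLS agrees", {
  co <- null_cohort()  # built with rho = 0
  est <- suppressWarnings(
    estimate_wage_effect(co, "physical", adjust_for = c("ses", "emotional"),
                         selection_covariates = c("ses", "dependants"),
                         n_boot = 0))
  expect_lt(abs(est$mills_coef), 3 * est$mills_coef_se)
  ols <- lm(log(wage) ~ physical + ses + emotional,
            data = co[co$participation == 1, ])
  expect_equal(est$proportional_reduction, 1 - exp(coef(ols)[["physical"]]),
               tolerance = 0.02)
})

test_that("selection-corrected wage reduction recovers the generating truth", {
  co <- reference_cohort()  # physical reduction 0.117, rho 0.5
  est <- estimate_wage_effect(
    co, "physical", adjust_for = c("female", "ses", "emotional"),
    selection_covariates = c("physical", "emotional", "female", "ses",
                             "dependants"),
    n_boot = 30, seed = 11)
  expect_lt(abs(est$proportional_reduction - 0.117), 3 * est$se)
  expect_gt(est$rho_hat, 0)  # positive selection correlation detected
  expect_lte(est$n_selected, nrow(co))
})

test_that("the bootstrap is reproducible under a fixed seed and warns without
           an exclusion restriction", {
  co <- generate_cohort(example_cohort_spec(3000, seed = 5))
  run <- function() estimate_wage_effect(
    co, "physical", adjust_for = c("female", "ses"),
    selection_covariates = c("female", "ses", "dependants"),
    n_boot = 10, seed = 77)
  expect_identical(run(), run())
  expect_warning(
    estimate_wage_effect(co, "physical", adjust_for = c("female", "ses"),
                         selection_covariates = c("female", "ses"),
                         n_boot = 0),
    "exclud")
})

test_that("wage estimation fails cleanly with no workers or separation", {
  co <- generate_cohort(example_cohort_spec(500, seed = 6))
  none <- co
  none$participation <- 0L
  none$wage <- NA_real_
  expect_error(
    estimate_wage_effect(none, "physical", selection_covariates = "ses",
                         n_boot = 0),
    "no wage")
  sep <- co
  sep$participation <- as.integer(sep$ses > 0)  # perfectly separated probit
  sep$wage <- ifelse(sep$participation == 1, 100, NA)
  expect_error(
    suppressWarnings(
      estimate_wage_effect(sep, "physical", selection_covariates = "ses",
                           n_boot = 0)),
    "separation")
})
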