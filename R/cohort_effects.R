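#' Estimate a relative risk from a cohort table
#'
#' Fits a log-link binomial model of the binary outcome on the binary
#' exposure and any confounders, so the exponentiated exposure coefficient is
#' a relative risk. Log-binomial likelihoods can fail to converge because the
#' log link does not respect the unit-interval constraint; on failure the
#' estimator falls back to a log-link Poisson (count) model with a
#' heteroskedasticity-robust (HC0 sandwich) variance, the standard
#' relative-risk regression fallback, and emits a warning naming the switch.
#'
#' With no confounders the fitted model is saturated over the 2x2 table and
#' the returned RR equals the closed-form crude risk ratio exactly.
#'
#' @param cohort A cohort table (from [generate_cohort()], [read_cohort()]
#'   or any data frame with 0/1 exposure and outcome columns).
#' @param exposure,outcome Column names of the binary exposure and outcome.
#' @param adjust_for Character vector of confounder column names.
#' @return A one-row tibble of class `rr_estimate` with columns `exposure`,
#'   `outcome`, `rr`, `log_rr_se`, `n` and `method`
#'   (`"log-binomial"` or `"robust-poisson"`).
#' @export
estimate_rr <- function(cohort, exposure, outcome, adjust_for = character()) {
  check_cols(cohort, c(exposure, outcome, adjust_for), "cohort")
  y <- cohort[[outcome]]
  x <- cohort[[exposure]]
  if (!all(y %in% c(0, 1)) || !all(x %in% c(0, 1))) {
    stop_input("exposure and outcome columns must be binary 0/1")
  }
  if (!any(x == 1) || !any(x == 0)) {
    stop_input(sprintf("both strata of '%s' must be non-empty", exposure))
  }
  events <- c(sum(y[x == 1]), sum(y[x == 0]))
  if (any(events == 0)) {
    stop_input(sprintf(
      "zero '%s' events in the %s stratum of '%s'; apply a continuity correction or pool strata before estimating",
      outcome, c("exposed", "unexposed")[events == 0][1], exposure))
  }

  rhs <- paste(c(exposure, adjust_for), collapse = " + ")
  fml <- as.formula(paste(outcome, "~", rhs))
  dat <- as.data.frame(cohort[, c(outcome, exposure, adjust_for)])

  # log-binomial needs feasible starting values; start at the crude model
  start <- c(log(mean(y)), rep(0, length(adjust_for) + 1))
  fit <- tryCatch({
    f <- suppressWarnings(
      glm(fml, family = binomial(link = "log"), data = dat, start = start))
    if (!f$converged || any(!is.finite(coef(f)))) stop("log-binomial did not converge")
    f
  }, error = function(e) NULL)

  if (!is.null(fit)) {
    method <- "log-binomial"
    se <- sqrt(diag(vcov(fit)))[[exposure]]
  } else {
    warning("log-binomial fit failed to converge; falling back to a ",
            "log-link Poisson model with robust (sandwich) variance",
            call. = FALSE)
    fit <- glm(fml, family = poisson(link = "log"), data = dat)
    method <- "robust-poisson"
    se <- sqrt(diag(sandwich::vcovHC(fit, type = "HC0")))[[exposure]]
  }

  res <- tibble::tibble(
    exposure = exposure,
    outcome = outcome,
    rr = unname(exp(coef(fit)[[exposure]])),
    log_rr_se = unname(se),
    n = nrow(dat),
    method = method
  )
  class(res) <- c("rr_estimate", class(res))
  res
}

#' Inverse Mills ratio
#'
#' `dnorm(x) / pnorm(x)`: the expected value of a standard-normal error given
#' truncation above `-x`, evaluated at the participation model's linear
#' predictor in the second stage of a Heckman selection correction. At 0 it
#' equals `sqrt(2/pi) = 0.7978846`.
#'
#' @param x Numeric vector of probit linear predictors.
#' @return Numeric vector of the same length.
#' @export
inverse_mills <- function(x) dnorm(x) / pnorm(x)

# Stage 2 of the Heckman correction: OLS of log wage on the covariates plus
# the inverse Mills ratio column. Exposed internally so the mills column can
# be forced to zero, in which case the fit is ordinary least squares.
heckman_stage2 <- function(dat, outcome_rhs, mills) {
  dat$.mills <- mills
  fml <- as.formula(paste("log(wage) ~", outcome_rhs, "+ .mills"))
  lm(fml, data = dat)
}

.fit_wage_once <- function(dat, exposure, adjust_for, selection_covariates) {
  sel_rhs <- paste(selection_covariates, collapse = " + ")
  probit <- suppressWarnings(
    glm(as.formula(paste("participation ~", sel_rhs)),
        family = binomial(link = "probit"), data = dat))
  p_hat <- predict(probit, type = "response")
  if (any(p_hat > 1 - 1e-10) || any(p_hat < 1e-10)) {
    stop_input("probit participation model shows (quasi-)separation: ",
               "fitted probabilities of 0 or 1")
  }
  lp <- predict(probit, type = "link")
  mills <- inverse_mills(lp)
  part <- dat$participation == 1
  stage2 <- heckman_stage2(dat[part, , drop = FALSE],
                           paste(c(exposure, adjust_for), collapse = " + "),
                           mills[part])
  b <- coef(stage2)
  beta_mills <- b[[".mills"]]
  # Heckman's consistent residual-variance estimate: sigma^2 = e'e/N +
  # beta_m^2 * mean(delta), delta_i = mills_i * (mills_i + lp_i)
  delta <- mills[part] * (mills[part] + lp[part])
  sigma2 <- mean(residuals(stage2)^2) + beta_mills^2 * mean(delta)
  rho_hat <- beta_mills / sqrt(sigma2)
  rho_hat <- max(-1, min(1, rho_hat))
  list(beta_exposure = b[[exposure]],
       beta_mills = beta_mills,
       rho_hat = rho_hat,
       n_selected = sum(part),
       stage1 = probit, stage2 = stage2)
}

#' Selection-corrected proportional wage reduction (Heckman two-stage)
#'
#' Estimates the proportional reduction in monthly earnings attributable to a
#' childhood violence exposure, correcting for non-random selection into paid
#' work. Stage 1 fits a probit participation model by maximum likelihood on
#' `selection_covariates`; stage 2 regresses log observed wage on the
#' exposure, confounders and the inverse Mills ratio evaluated at the stage-1
#' linear predictors. The reduction is `1 - exp(beta_exposure)` from the
#' log-wage equation, so a positive value is an earnings loss. Standard
#' errors come from a nonparametric bootstrap over individuals (or over
#' clusters when `cluster` names a column), which accounts for the estimated
#' first-stage regressor.
#'
#' At least one selection covariate should be excluded from the wage equation
#' (an exclusion restriction); without one the correction is identified only
#' by the nonlinearity of the Mills ratio and a warning is issued.
#'
#' @param cohort Cohort table with `participation` and `wage` columns.
#' @param exposure Binary exposure column name.
#' @param adjust_for Confounder column names for the wage equation.
#' @param selection_covariates Column names for the participation probit.
#' @param n_boot Bootstrap replicates for the standard error (default 200).
#' @param seed Optional integer seed making the bootstrap reproducible.
#' @param cluster Optional column name; bootstrap resamples whole clusters.
#' @return A one-row tibble of class `wage_effect` with columns `exposure`,
#'   `proportional_reduction`, `se`, `rho_hat`, `mills_coef`,
#'   `mills_coef_se`, `n_selected` and `n`.
#' @export
estimate_wage_effect <- function(cohort, exposure,
                                 adjust_for = character(),
                                 selection_covariates,
                                 n_boot = 200,
                                 seed = NULL,
                                 cluster = NULL) {
  check_cols(cohort, c(exposure, adjust_for, selection_covariates,
                       "participation", "wage", cluster), "cohort")
  if (!any(cohort$participation == 1)) {
    stop_input("no wage observations: nobody participates")
  }
  excluded <- setdiff(selection_covariates, c(exposure, adjust_for))
  if (!length(excluded)) {
    warning("no selection covariate is excluded from the wage equation; ",
            "the correction is identified only through the Mills-ratio ",
            "nonlinearity", call. = FALSE)
  }
  dat <- as.data.frame(cohort)
  point <- .fit_wage_once(dat, exposure, adjust_for, selection_covariates)

  boot_one <- function(d) {
    tryCatch(
      1 - exp(.fit_wage_once(d, exposure, adjust_for,
                             selection_covariates)$beta_exposure),
      error = function(e) NA_real_)
  }
  resample <- function() {
    if (is.null(cluster)) {
      dat[sample.int(nrow(dat), replace = TRUE), , drop = FALSE]
    } else {
      ids <- unique(dat[[cluster]])
      take <- sample(ids, length(ids), replace = TRUE)
      do.call(rbind, lapply(take, function(i) dat[dat[[cluster]] == i, , drop = FALSE]))
    }
  }
  run_boot <- function() {
    vapply(seq_len(n_boot), function(i) boot_one(resample()), numeric(1))
  }
  boots <- if (n_boot > 0) {
    if (is.null(seed)) run_boot() else with_local_seed(seed, run_boot())
  } else {
    numeric(0)
  }
  se <- if (length(boots)) sd(boots, na.rm = TRUE) else NA_real_
  # Mills-coefficient SE from the stage-2 OLS vcov: approximate, used only
  # for the rho ~ 0 diagnostic; the headline SE is the bootstrap one.
  mills_se <- sqrt(diag(vcov(point$stage2)))[[".mills"]]

  res <- tibble::tibble(
    exposure = exposure,
    proportional_reduction = 1 - exp(point$beta_exposure),
    se = se,
    rho_hat = point$rho_hat,
    mills_coef = point$beta_mills,
    mills_coef_se = mills_se,
    n_selected = point$n_selected,
    n = nrow(dat)
  )
  class(res) <- c("wage_effect", class(res))
  res
}

#' Write estimated effects as CSV
#'
#' Flattens `rr_estimate` / `wage_effect` rows to the common export layout
#' (exposure, outcome, estimate, se, n).
#'
#' @param effects A tibble of estimates (rows from [estimate_rr()] or
#'   [estimate_wage_effect()], possibly bound together).
#' @param path File path.
#' @export
write_effects <- function(effects, path) {
  out <- tibble::tibble(
    exposure = effects$exposure,
    outcome = if ("outcome" %in% names(effects)) effects$outcome else "wage",
    estimate = if ("rr" %in% names(effects)) effects$rr
               else effects$proportional_reduction,
    se = if ("log_rr_se" %in% names(effects)) effects$log_rr_se else effects$se,
    n = effects$n
  )
  write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(path)
}
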