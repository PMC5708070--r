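#' Specify a synthetic youth cohort
#'
#' Builds and validates the specification for a synthetic cross-sectional
#' cohort emulating a Cape-Town-style youth panel: binary childhood violence
#' exposures, socio-demographic confounders, binary adult outcomes generated
#' under a log-risk model (so outcome coefficients are log relative risks),
#' and monthly wages observed only for labour-force participants, with the
#' participation (probit) error correlated with the wage error. Because every
#' generating parameter is known, downstream estimators can be validated by
#' parameter recovery.
#'
#' @param n_individuals Positive integer, cohort size.
#' @param exposures Named numeric vector of lifetime exposure prevalences in
#'   `[0, 1]`, one per violence type. Exposures are drawn independently
#'   across types.
#' @param confounders Named list; each element is a list with `dist` in
#'   `"bernoulli"`, `"categorical"` or `"normal"` and its parameters
#'   (`p` for bernoulli; `levels` and `p` for categorical; standard normal
#'   takes none).
#' @param outcomes Named list; each element has `intercept` (log baseline
#'   risk), `log_rr` (named log-relative-risk per exposure) and optional
#'   `confounders` (named log-risk coefficients). Risk is
#'   `exp(intercept + sum(coef * covariate))`.
#' @param wage List with `intercept` (log monthly wage), `reductions`
#'   (named proportional wage reduction per exposure, each in `[0, 1)`;
#'   applied multiplicatively as `(1 - reduction)^exposure`), optional
#'   `confounders` (named log-wage coefficients) and `sigma` (residual SD of
#'   log wage).
#' @param selection List with `intercept`, optional named `exposures` and
#'   `confounders` probit coefficients for labour-force participation, and
#'   `rho`, the correlation between the participation and wage errors,
#'   strictly inside `(-1, 1)`.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec and seed.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [example_cohort_spec()]
#' @export
#' @examples
#' spec <- cohort_spec(
#'   n_individuals = 500,
#'   exposures = c(physical = 0.26),
#'   confounders = list(ses = list(dist = "normal")),
#'   outcomes = list(anxiety = list(intercept = log(0.1),
#'                                  log_rr = c(physical = log(1.6)),
#'                                  confounders = c(ses = 0.1))),
#'   wage = list(intercept = log(3000), reductions = c(physical = 0.117),
#'               confounders = c(ses = 0.3), sigma = 0.6),
#'   selection = list(intercept = 0.3, confounders = c(ses = 0.3), rho = 0.5),
#'   seed = 1
#' )
cohort_spec <- function(n_individuals,
                        exposures,
                        confounders = list(),
                        outcomes = list(),
                        wage = NULL,
                        selection = NULL,
                        seed = 1L) {
  spec <- structure(
    list(
      n_individuals = n_individuals,
      exposures = exposures,
      confounders = confounders,
      outcomes = outcomes,
      wage = wage,
      selection = selection,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

# Worst-case value a covariate can take in the log-risk bound: binary and
# categorical covariates are bounded by construction; continuous standard
# normal is bounded at +/- 4 SD for validation (risks are also checked on
# the realised draws at generation time).
.covariate_bound <- function(conf) {
  switch(conf$dist,
         bernoulli = c(0, 1),
         categorical = range(conf$levels %||% seq_along(conf$p) - 1),
         normal = c(-4, 4),
         stop_input(sprintf("unknown confounder distribution '%s'", conf$dist)))
}

validate_cohort_spec <- function(spec) {
  if (!is.numeric(spec$n_individuals) || length(spec$n_individuals) != 1 ||
      spec$n_individuals < 1 || spec$n_individuals != round(spec$n_individuals)) {
    stop_input("`n_individuals` must be a positive integer count")
  }
  if (is.null(names(spec$exposures)) || any(names(spec$exposures) == "")) {
    stop_input("`exposures` must be a named vector of prevalences")
  }
  for (nm in names(spec$exposures)) {
    check_prob(spec$exposures[[nm]], paste0("exposures$", nm))
  }
  for (nm in names(spec$confounders)) {
    conf <- spec$confounders[[nm]]
    if (is.null(conf$dist)) {
      stop_input(sprintf("confounder '%s' has no `dist`", nm))
    }
    if (conf$dist == "bernoulli") check_prob(conf$p, paste0(nm, "$p"))
    if (conf$dist == "categorical") {
      check_prob(conf$p, paste0(nm, "$p"))
      if (abs(sum(conf$p) - 1) > 1e-8) {
        stop_input(sprintf("confounder '%s' probabilities must sum to 1", nm))
      }
    }
    .covariate_bound(conf)
  }
  for (nm in names(spec$outcomes)) {
    out <- spec$outcomes[[nm]]
    if (is.null(out$intercept)) {
      stop_input(sprintf("outcome '%s' has no `intercept`", nm))
    }
    bad_exp <- setdiff(names(out$log_rr), names(spec$exposures))
    if (length(bad_exp)) {
      stop_input(sprintf("outcome '%s' references unknown exposure(s): %s",
                         nm, paste(bad_exp, collapse = ", ")))
    }
    bad_conf <- setdiff(names(out$confounders), names(spec$confounders))
    if (length(bad_conf)) {
      stop_input(sprintf("outcome '%s' references unknown confounder(s): %s",
                         nm, paste(bad_conf, collapse = ", ")))
    }
    # worst-case implied risk on the log scale must stay within [0, 1]
    worst <- out$intercept
    for (coefs in list(out$log_rr, out$confounders)) {
      for (cn in names(coefs)) {
        b <- coefs[[cn]]
        bound <- if (cn %in% names(spec$exposures)) c(0, 1) else
          .covariate_bound(spec$confounders[[cn]])
        worst <- worst + max(b * bound)
      }
    }
    if (worst > 0) {
      stop_input(sprintf(
        "outcome '%s': worst-case implied risk exp(%.4f) = %.4f exceeds 1; %s",
        nm, worst, exp(worst),
        "lower the intercept or the log-RR coefficients"))
    }
  }
  if (!is.null(spec$wage)) {
    for (nm in names(spec$wage$reductions)) {
      r <- spec$wage$reductions[[nm]]
      if (!is.numeric(r) || r < 0 || r >= 1) {
        stop_input(sprintf("wage reduction for '%s' must lie in [0, 1); got %s",
                           nm, format(r)))
      }
    }
    check_positive(spec$wage$sigma %||% 1, "wage$sigma")
    if (is.null(spec$selection)) {
      stop_input("a `wage` model requires a `selection` model")
    }
  }
  if (!is.null(spec$selection)) {
    rho <- spec$selection$rho %||% 0
    if (!is.numeric(rho) || abs(rho) >= 1) {
      stop_input(sprintf("selection$rho must lie strictly inside (-1, 1); got %s",
                         format(rho)))
    }
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  n:", x$n_individuals, " seed:", x$seed, "\n")
  cat("  exposures:", paste(sprintf("%s=%.3g", names(x$exposures), x$exposures),
                            collapse = ", "), "\n")
  cat("  confounders:", paste(names(x$confounders), collapse = ", "), "\n")
  cat("  outcomes:", paste(names(x$outcomes), collapse = ", "), "\n")
  if (!is.null(x$wage)) {
    cat("  wage reductions:",
        paste(sprintf("%s=%.3g", names(x$wage$reductions), x$wage$reductions),
              collapse = ", "),
        sprintf(" (sigma=%.3g, rho=%.3g)\n", x$wage$sigma %||% 1,
                x$selection$rho %||% 0))
  }
  invisible(x)
}

#' Default synthetic cohort emulating the South African study conditions
#'
#' Study-condition defaults: physical- and emotional-violence prevalences from
#' the national survey totals (26.1% and 12.6%); alcohol-abuse and anxiety
#' outcomes with relative risks on the scale of the pooled national estimates
#' (1.55 and 1.86); proportional wage reductions of 11.7% (physical) and 9.2%
#' (emotional); participation-wage error correlation 0.5. Confounders are a
#' binary `female` indicator, a standard-normal socioeconomic index `ses`,
#' and a standard-normal `dependants` index that enters only the
#' participation equation, giving estimators an exclusion restriction.
#'
#' @param n_individuals Cohort size (default 50000, the size at which the
#'   recovery checks are run).
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
example_cohort_spec <- function(n_individuals = 50000, seed = 1L) {
  cohort_spec(
    n_individuals = n_individuals,
    exposures = c(physical = 0.261, emotional = 0.126),
    confounders = list(
      female = list(dist = "bernoulli", p = 0.5),
      ses = list(dist = "normal"),
      dependants = list(dist = "normal")
    ),
    outcomes = list(
      alcohol_abuse = list(
        intercept = log(0.08),
        log_rr = c(physical = log(1.55), emotional = log(1.35)),
        confounders = c(ses = 0.10)
      ),
      anxiety = list(
        intercept = log(0.10),
        log_rr = c(physical = log(1.57), emotional = log(1.86)),
        confounders = c(ses = 0.10, female = 0.15)
      )
    ),
    wage = list(
      intercept = log(3000),
      reductions = c(physical = 0.117, emotional = 0.092),
      confounders = c(female = -0.25, ses = 0.30),
      sigma = 0.6
    ),
    selection = list(
      intercept = 0.3,
      exposures = c(physical = 0, emotional = 0),
      confounders = c(female = -0.2, ses = 0.3, dependants = -0.4),
      rho = 0.5
    ),
    seed = seed
  )
}

.draw_confounder <- function(conf, n) {
  switch(conf$dist,
         bernoulli = rbinom(n, 1, conf$p),
         categorical = sample(conf$levels %||% (seq_along(conf$p) - 1),
                              n, replace = TRUE, prob = conf$p),
         normal = rnorm(n))
}

.linear_predictor <- function(intercept, coefs, data) {
  lp <- rep(intercept, nrow(data))
  for (nm in names(coefs)) lp <- lp + coefs[[nm]] * data[[nm]]
  lp
}

#' Generate a synthetic cohort
#'
#' Draws one cross-sectional cohort from a [cohort_spec()]: independent
#' Bernoulli exposures at the stated prevalences, confounders from their
#' stated distributions, binary outcomes with risk
#' `exp(intercept + sum(coef * covariate))` (any realised risk above 1 is an
#' error, never silently truncated, because truncation would bias recovery
#' tests), a probit participation indicator, and a log-normal monthly wage
#' multiplied by `(1 - reduction)` for each exposure suffered. The
#' participation and log-wage errors are bivariate normal with correlation
#' `rho`; the wage is observed (non-missing) exactly when participation is 1.
#'
#' @param spec A [cohort_spec()].
#' @param keep_latents If `TRUE`, retain the latent error draws as columns
#'   `.participation_resid` (standard-normal probit error) and `.wage_resid`
#'   (log-wage error) so tests can instrument the selection structure
#'   directly.
#' @return A tibble (class `cohort_table`), one row per individual.
#' @export
generate_cohort <- function(spec, keep_latents = FALSE) {
  validate_cohort_spec(spec)
  n <- spec$n_individuals
  with_local_seed(spec$seed, {
    tab <- list()
    for (nm in names(spec$exposures)) {
      tab[[nm]] <- rbinom(n, 1, spec$exposures[[nm]])
    }
    for (nm in names(spec$confounders)) {
      tab[[nm]] <- .draw_confounder(spec$confounders[[nm]], n)
    }
    tab <- tibble::as_tibble(tab)
    for (nm in names(spec$outcomes)) {
      out <- spec$outcomes[[nm]]
      lp <- .linear_predictor(out$intercept, c(out$log_rr, out$confounders), tab)
      risk <- exp(lp)
      if (any(risk > 1)) {
        stop_input(sprintf(
          "outcome '%s': realised risk exceeds 1 for %d individual(s) (max %.4f); refusing to truncate",
          nm, sum(risk > 1), max(risk)))
      }
      tab[[nm]] <- rbinom(n, 1, risk)
    }
    if (!is.null(spec$wage)) {
      sel <- spec$selection
      rho <- sel$rho %||% 0
      sigma <- spec$wage$sigma %||% 1
      # bivariate-normal errors: e_sel ~ N(0,1); e_wage = sigma*(rho*e_sel +
      # sqrt(1-rho^2)*z) so cor(e_sel, e_wage) = rho
      e_sel <- rnorm(n)
      e_wage <- sigma * (rho * e_sel + sqrt(1 - rho^2) * rnorm(n))
      lp_sel <- .linear_predictor(sel$intercept,
                                  c(sel$exposures, sel$confounders), tab)
      participation <- as.integer(lp_sel + e_sel > 0)
      lp_wage <- .linear_predictor(spec$wage$intercept, spec$wage$confounders, tab)
      for (nm in names(spec$wage$reductions)) {
        lp_wage <- lp_wage + log(1 - spec$wage$reductions[[nm]]) * tab[[nm]]
      }
      wage <- exp(lp_wage + e_wage)
      wage[participation == 0] <- NA_real_
      tab$participation <- participation
      tab$wage <- wage
      if (keep_latents) {
        tab$.participation_resid <- e_sel
        tab$.wage_resid <- e_wage
      }
    }
    structure(tab,
              class = c("cohort_table", class(tab)),
              cohort_spec = spec)
  })
}

#' Empirical summaries of a cohort table
#'
#' Computes empirical exposure prevalences, outcome risks by exposure stratum
#' with the crude relative risk `risk(exposed) / risk(unexposed)`, mean log
#' wage by stratum, and the participation rate. Strata with no individuals
#' (or crude RRs whose unexposed risk is zero) are reported as `NA`, never as
#' zero.
#'
#' @param cohort A cohort table from [generate_cohort()] or [read_cohort()].
#' @param exposures,outcomes Character vectors of column names; default to
#'   the generating spec when the table carries one.
#' @return A list with elements `prevalence`, `risks` (tibble of exposure,
#'   outcome, stratum risks and `crude_rr`), `wages` (mean log wage by
#'   stratum) and `participation_rate`.
#' @export
empirical_summary <- function(cohort, exposures = NULL, outcomes = NULL) {
  if (nrow(cohort) == 0) stop_input("cohort is empty")
  spec <- attr(cohort, "cohort_spec")
  exposures <- exposures %||% names(spec$exposures)
  outcomes <- outcomes %||% names(spec$outcomes)
  if (is.null(exposures)) {
    stop_input("`exposures` must be given when the table has no attached spec")
  }
  check_cols(cohort, exposures, "cohort")
  check_cols(cohort, outcomes, "cohort")

  prevalence <- vapply(exposures, function(e) mean(cohort[[e]]), numeric(1))

  strat <- function(e, o) {
    exp_rows <- cohort[[e]] == 1
    r1 <- if (any(exp_rows)) mean(cohort[[o]][exp_rows]) else NA_real_
    r0 <- if (any(!exp_rows)) mean(cohort[[o]][!exp_rows]) else NA_real_
    rr <- if (!is.na(r1) && !is.na(r0) && r0 > 0) r1 / r0 else NA_real_
    tibble::tibble(exposure = e, outcome = o,
                   risk_exposed = r1, risk_unexposed = r0, crude_rr = rr)
  }
  risks <- if (length(outcomes)) {
    dplyr::bind_rows(lapply(exposures, function(e) {
      dplyr::bind_rows(lapply(outcomes, function(o) strat(e, o)))
    }))
  } else {
    tibble::tibble()
  }

  wages <- NULL
  participation_rate <- NULL
  if ("wage" %in% names(cohort)) {
    participation_rate <- mean(cohort$participation)
    wages <- dplyr::bind_rows(lapply(exposures, function(e) {
      w <- log(cohort$wage)
      exp_rows <- cohort[[e]] == 1
      tibble::tibble(
        exposure = e,
        mean_log_wage_exposed = if (any(exp_rows & !is.na(w)))
          mean(w[exp_rows], na.rm = TRUE) else NA_real_,
        mean_log_wage_unexposed = if (any(!exp_rows & !is.na(w)))
          mean(w[!exp_rows], na.rm = TRUE) else NA_real_)
    }))
  }
  list(prevalence = prevalence, risks = risks, wages = wages,
       participation_rate = participation_rate)
}

#' Read a cohort specification from a YAML file
#'
#' The file mirrors the arguments of [cohort_spec()] as nested keys.
#'
#' @param path Path to a YAML file.
#' @return A validated `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  as_named_num <- function(x) if (is.null(x)) NULL else unlist(x)
  outcomes <- lapply(raw$outcomes, function(o) {
    list(intercept = o$intercept,
         log_rr = as_named_num(o$log_rr),
         confounders = as_named_num(o$confounders))
  })
  wage <- if (!is.null(raw$wage)) {
    list(intercept = raw$wage$intercept,
         reductions = as_named_num(raw$wage$reductions),
         confounders = as_named_num(raw$wage$confounders),
         sigma = raw$wage$sigma)
  }
  selection <- if (!is.null(raw$selection)) {
    list(intercept = raw$selection$intercept,
         exposures = as_named_num(raw$selection$exposures),
         confounders = as_named_num(raw$selection$confounders),
         rho = raw$selection$rho)
  }
  cohort_spec(
    n_individuals = raw$n_individuals,
    exposures = as_named_num(raw$exposures),
    confounders = raw$confounders %||% list(),
    outcomes = outcomes %||% list(),
    wage = wage,
    selection = selection,
    seed = raw$seed %||% 1L
  )
}

#' Write / read a cohort table as CSV
#'
#' Missing wages (non-participants) are written as empty fields.
#'
#' @param cohort A cohort table.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   tibble of class `cohort_table` (without an attached generating spec).
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if ("wage" %in% names(tab) && "participation" %in% names(tab)) {
    bad <- xor(is.na(tab$wage), tab$participation == 0)
    if (any(bad)) {
      stop_input("cohort file violates wage-participation consistency: ",
                 sum(bad), " row(s) have a wage without participation (or vice versa)")
    }
  }
  structure(tab, class = c("cohort_table", class(tab)))
}
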