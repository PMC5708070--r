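#' Aggregate provincial child-welfare spending
#'
#' Exact integer sum of the provincial child care and protection amounts.
#'
#' @param spends Tibble `(province, amount_thousand)`, amounts in thousand
#'   currency units.
#' @return Total spend in thousand currency units.
#' @export
aggregate_welfare <- function(spends) {
  check_cols(spends, c("province", "amount_thousand"), "welfare table")
  if (nrow(spends) == 0) stop_input("welfare table is empty")
  check_non_negative(spends$amount_thousand, "amount_thousand")
  sum(spends$amount_thousand)
}

#' Assemble a pipeline configuration
#'
#' Collects every input of the end-to-end analysis. The default is the
#' bundled 2015 South African configuration: published prevalence and RR
#' tables, synthetic (reverse-derived) baseline DALYs, standard life table,
#' 2009 homicide counts, Treasury welfare spending, and the earnings-chain
#' parameters. Witnessing family violence and exploitation are excluded
#' from totals by default (too few consequence studies support them);
#' override `include_exposures` to change that.
#'
#' @param prevalence Tibble `(exposure, sex, p)`.
#' @param rr_table Pooled RR tibble `(exposure, outcome, sex, rr)`; ignored
#'   when `study_effects` or `cohort_spec` supplies effects instead.
#' @param study_effects Optional [study_effects()] table pooled via
#'   [harmonise_effects()] and [pool_rr_table()].
#' @param p0_table,adjustment_ratios,pooling_scale,rare_outcome Passed to
#'   the harmonisation/pooling stage when `study_effects` is used.
#' @param cohort_spec Optional [cohort_spec()]: relative risks are then
#'   estimated from a generated cohort with [estimate_rr()] (one RR per
#'   exposure x outcome in the spec), and prevalence defaults to the spec's
#'   exposure prevalences.
#' @param baseline Baseline DALY tibble `(outcome, sex, dalys)` (optionally
#'   with `exposure`); default is the synthetic derived table.
#' @param exclusions,contributions Double-count removal inputs for
#'   [attribute_dalys()]. The default exclusion map encodes the published
#'   example: self-harm and HIV/AIDS contributions removed under drug use.
#' @param overlap Umbrella-outcome map for [aggregate_burden()].
#' @param include_exposures Character vector of exposures entering totals.
#' @param life_table,homicides Fatal-burden inputs.
#' @param econ An [econ_params()].
#' @param wage_reductions Named vector of proportional monthly-earnings
#'   reductions per exposure (defaults: physical 0.117, emotional 0.092).
#' @param welfare Welfare-spend tibble.
#' @param seed Integer seed for any stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(prevalence = za_prevalence(),
                            rr_table = za_effect_table(),
                            study_effects = NULL,
                            p0_table = NULL,
                            adjustment_ratios = NULL,
                            pooling_scale = "log",
                            rare_outcome = FALSE,
                            cohort_spec = NULL,
                            baseline = NULL,
                            exclusions = list(drug_abuse = c("self_harm", "hiv")),
                            contributions = NULL,
                            overlap = list(serious_mental_illness =
                                             c("anxiety", "depression")),
                            include_exposures = c("sexual_violence",
                                                  "physical_violence",
                                                  "emotional_violence",
                                                  "neglect"),
                            life_table = za_life_table(),
                            homicides = za_homicide_counts(),
                            econ = za_econ_params(),
                            wage_reductions = c(physical_violence = 0.117,
                                                emotional_violence = 0.092),
                            welfare = za_welfare_spend(),
                            seed = 1L) {
  if (!length(include_exposures)) {
    stop_input("`include_exposures` must name at least one exposure")
  }
  if (is.null(baseline) && is.null(cohort_spec)) {
    baseline <- za_baseline_dalys_synthetic(effects = rr_table,
                                            prevalences = prevalence)
  }
  structure(list(prevalence = prevalence, rr_table = rr_table,
                 study_effects = study_effects, p0_table = p0_table,
                 adjustment_ratios = adjustment_ratios,
                 pooling_scale = pooling_scale, rare_outcome = rare_outcome,
                 cohort_spec = cohort_spec, baseline = baseline,
                 exclusions = exclusions, contributions = contributions,
                 overlap = overlap, include_exposures = include_exposures,
                 life_table = life_table, homicides = homicides,
                 econ = econ, wage_reductions = wage_reductions,
                 welfare = welfare, seed = as.integer(seed)),
            class = "pipeline_config")
}

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[vacburden] ", fmt), ...))
}

#' Run the full burden-estimation pipeline
#'
#' Executes, in order: effect pooling (or cohort-based effect estimation),
#' attributable fractions, stratum selection, nonfatal DALY attribution and
#' aggregation, fatal DALYs through the life table, human-capital
#' monetisation, the earnings-loss chain, and welfare-spend aggregation.
#' Re-running with the same configuration and seed is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log each stage and every design-mode in effect to the
#'   message stream.
#' @return A list of class `vac_report`: `pafs`, `attributed`, `burden`
#'   (cells/totals/grand total), `fatal` (dalys and value), `earnings`,
#'   `welfare_thousand`, `grand` (headline totals) and `modes` (the
#'   design-decision modes applied).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  modes <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_input(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- effects -------------------------------------------------------------
  prevalence <- config$prevalence
  if (!is.null(config$cohort_spec)) {
    .log_stage(verbose, "simulating cohort (n = %d, seed = %d)",
               config$cohort_spec$n_individuals, config$cohort_spec$seed)
    pooled <- stage("effects", {
      cohort <- generate_cohort(config$cohort_spec)
      spec <- config$cohort_spec
      ests <- dplyr::bind_rows(lapply(names(spec$outcomes), function(o) {
        # adjust each outcome model for the confounders that enter it
        adj <- names(spec$outcomes[[o]]$confounders)
        dplyr::bind_rows(lapply(names(spec$exposures), function(e) {
          estimate_rr(cohort, e, o, adjust_for = adj %||% character())
        }))
      }))
      tibble::tibble(exposure = ests$exposure, outcome = ests$outcome,
                     sex = "total", rr = ests$rr)
    })
    prevalence <- tibble::tibble(
      exposure = names(config$cohort_spec$exposures),
      sex = "total",
      p = unname(config$cohort_spec$exposures))
    modes$rr_source <- "synthetic-cohort"
  } else if (!is.null(config$study_effects)) {
    .log_stage(verbose, "pooling %d study effects (%s scale)",
               nrow(config$study_effects), config$pooling_scale)
    pooled <- stage("pooling", {
      harm <- harmonise_effects(config$study_effects,
                                p0_table = config$p0_table,
                                adjustment_ratios = config$adjustment_ratios,
                                rare_outcome = config$rare_outcome)
      pool_rr_table(harm, scale = config$pooling_scale)
    })
    modes$rr_source <- "pooled-study-effects"
    modes$pooling_scale <- config$pooling_scale
    if (config$rare_outcome) modes$or_conversion <- "rare-outcome"
  } else {
    pooled <- config$rr_table
    modes$rr_source <- "supplied-rr-table"
  }

  # --- attributable fractions ---------------------------------------------
  .log_stage(verbose, "computing attributable fractions for %d RR cells",
             nrow(pooled))
  pafs <- stage("paf", build_paf_table(prevalence, pooled))
  pafs <- pafs[pafs$exposure %in% config$include_exposures, , drop = FALSE]
  selected <- select_paf_strata(pafs)
  modes$stratum_application <- attr(selected, "application_mode")
  modes$excluded_exposures <- setdiff(unique(pooled$exposure),
                                      config$include_exposures)

  # --- nonfatal burden -----------------------------------------------------
  .log_stage(verbose, "attributing baseline DALYs (%d strata)", nrow(selected))
  attributed <- stage("burden", attribute_dalys(selected, config$baseline,
                                                exclusions = config$exclusions,
                                                contributions = config$contributions))
  burden <- aggregate_burden(attributed, overlap = config$overlap,
                             gdp_per_capita = config$econ$gdp_per_capita)
  modes$overlap_map <- config$overlap
  modes$exclusion_map <- config$exclusions

  # --- fatal burden --------------------------------------------------------
  fatal <- stage("fatal", fatal_dalys(config$homicides, config$life_table))
  fatal_value <- monetise(fatal, config$econ$gdp_per_capita)
  .log_stage(verbose, "fatal DALYs: %.0f", fatal)

  # --- earnings ------------------------------------------------------------
  earnings <- stage("earnings", {
    dplyr::bind_rows(lapply(names(config$wage_reductions), function(e) {
      p <- prevalence$p[prevalence$exposure == e & prevalence$sex == "total"]
      if (!length(p)) stop_input(sprintf("no total-sex prevalence for '%s'", e))
      productivity_loss(p, config$wage_reductions[[e]], config$econ,
                        exposure = e)
    }))
  })

  # --- welfare -------------------------------------------------------------
  welfare_total <- stage("welfare", aggregate_welfare(config$welfare))

  # direct product: the grand total can dip below zero when estimated RRs
  # sit under 1 (protective point estimates), which monetise() rejects
  nonfatal_value <- burden$grand_total * config$econ$gdp_per_capita
  grand <- list(
    nonfatal_dalys = burden$grand_total,
    fatal_dalys = fatal,
    total_dalys = burden$grand_total + fatal,
    nonfatal_value = nonfatal_value,
    fatal_value = fatal_value,
    total_value = nonfatal_value + fatal_value,
    annual_earnings_loss = sum(earnings$annual_loss),
    welfare_spend = welfare_total * 1e3,
    value_share_of_gdp = if (is.null(config$econ$gdp_total)) NA_real_
      else (nonfatal_value + fatal_value) / config$econ$gdp_total
  )
  if (verbose) {
    for (nm in names(modes)) {
      .log_stage(TRUE, "mode %s: %s", nm,
                 paste(utils::capture.output(utils::str(modes[[nm]],
                                                        give.head = FALSE)),
                       collapse = " "))
    }
  }
  structure(list(pafs = pafs, attributed = attributed, burden = burden,
                 fatal = list(dalys = fatal, value = fatal_value),
                 earnings = earnings, welfare_thousand = welfare_total,
                 grand = grand, modes = modes, config = config),
            class = "vac_report")
}

#' @export
print.vac_report <- function(x, ...) {
  fmt_bn <- function(v) sprintf("ZAR %.1f bn", v / 1e9)
  g <- x$grand
  cat("Economic burden of violence against children\n")
  cat("--------------------------------------------\n")
  cat(sprintf("Nonfatal attributable DALYs : %s\n",
              format(round(g$nonfatal_dalys), big.mark = ",")))
  cat(sprintf("Fatal DALYs (homicides)     : %s\n",
              format(round(g$fatal_dalys), big.mark = ",")))
  cat(sprintf("Economic value of DALYs     : %s (nonfatal %s + fatal %s)\n",
              fmt_bn(g$total_value), fmt_bn(g$nonfatal_value),
              fmt_bn(g$fatal_value)))
  if (!is.na(g$value_share_of_gdp)) {
    cat(sprintf("  as share of GDP           : %.1f%%\n",
                100 * g$value_share_of_gdp))
  }
  for (i in seq_len(nrow(x$earnings))) {
    cat(sprintf("Annual earnings loss, %-18s: %s\n",
                x$earnings$exposure[i], fmt_bn(x$earnings$annual_loss[i])))
  }
  cat(sprintf("Child welfare spend         : %s\n",
              fmt_bn(x$welfare_thousand * 1e3)))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the machine-readable CSVs (attributable fractions, burden cells and
#' totals, earnings rows) plus a plain-text summary, into `dir`.
#'
#' @param report A `vac_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(tab, name) {
    write.csv(as.data.frame(tab), file.path(dir, name), row.names = FALSE)
  }
  w(report$pafs, "attributable_fractions.csv")
  w(report$burden$cells, "burden_cells.csv")
  w(report$burden$totals, "burden_totals.csv")
  w(report$earnings, "earnings_loss.csv")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
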