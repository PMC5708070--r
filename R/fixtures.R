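.extdata <- function(file) {
  path <- system.file("extdata", file, package = "vacburden")
  if (path == "") stop_input("bundled table not found: ", file)
  path
}

#' Bundled South African reference tables
#'
#' Accessors for the plain-text tables shipped with the package, covering a
#' 2015 national analysis: lifetime violence-exposure prevalence by sex from
#' a nationally representative survey; pooled relative risks with their
#' published attributable fractions; the published attributable-burden table
#' (DALY and million-Rand cells, plus the per-exposure totals row);
#' provincial child care and protection spending (thousand ZAR, fiscal year
#' 2015/2016); standard life-table anchors for years of life lost at ages
#' 2, 7, 12 and 16; and child homicide counts by age band (2009, the latest
#' available study year, carried forward to 2015).
#'
#' @return A tibble (or, for `za_econ_params()`, an [econ_params()]).
#' @name za_tables
NULL

#' @rdname za_tables
#' @export
za_prevalence <- function() {
  tibble::as_tibble(read.csv(.extdata("za_prevalence.csv"),
                             stringsAsFactors = FALSE))
}

#' @rdname za_tables
#' @param include_witnessing Keep the witnessing-family-violence rows, which
#'   have published RRs but no matching prevalence row and are excluded from
#'   burden totals.
#' @export
za_effect_table <- function(include_witnessing = FALSE) {
  tab <- tibble::as_tibble(read.csv(.extdata("za_rr_paf.csv"),
                                    stringsAsFactors = FALSE))
  if (!include_witnessing) {
    tab <- tab[tab$exposure != "witnessing_family_violence", , drop = FALSE]
  }
  tab
}

#' @rdname za_tables
#' @export
za_burden_cells <- function() {
  tibble::as_tibble(read.csv(.extdata("za_burden_cells.csv"),
                             stringsAsFactors = FALSE))
}

#' @rdname za_tables
#' @export
za_burden_totals <- function() {
  tibble::as_tibble(read.csv(.extdata("za_burden_totals.csv"),
                             stringsAsFactors = FALSE))
}

#' @rdname za_tables
#' @export
za_welfare_spend <- function() {
  tibble::as_tibble(read.csv(.extdata("za_welfare.csv"),
                             stringsAsFactors = FALSE))
}

#' @rdname za_tables
#' @export
za_life_table <- function() {
  tab <- read.csv(.extdata("za_life_table.csv"))
  life_table(tab$age, tab$yll)
}

#' @rdname za_tables
#' @export
za_homicide_counts <- function() {
  tibble::as_tibble(read.csv(.extdata("za_homicides.csv")))
}

#' @rdname za_tables
#' @export
za_econ_params <- function() {
  raw <- yaml::read_yaml(.extdata("za_econ.yaml"))
  gdp_pc <- raw$gdp_per_capita
  if (is.null(gdp_pc)) {
    tot <- za_burden_totals()
    all_row <- tot[tot$exposure == "all", ]
    gdp_pc <- all_row$value_million * 1e6 / all_row$daly_loss
  }
  econ_params(
    gdp_per_capita = gdp_pc,
    gdp_total = raw$gdp_total,
    median_monthly_earnings_base = raw$median_monthly_earnings_base,
    cpi_ratio = raw$earnings_target_year / raw$median_monthly_earnings_base,
    labour_force = raw$labour_force,
    exchange_rate = raw$exchange_rate
  )
}

#' Select the attributable-fraction strata used for burden attribution
#'
#' Published RR tables often print a total-sex estimate alongside
#' sex-specific ones for the same exposure and outcome. Attribution must not
#' count both: for each (exposure, outcome) cell this keeps the total-sex
#' record when one exists and otherwise keeps the sex-specific records,
#' whose contributions are later summed. The rule applied is recorded in the
#' `application_mode` attribute of the result.
#'
#' @param pafs Tibble `(exposure, outcome, sex, ...)`.
#' @return The filtered tibble, with attribute `application_mode`.
#' @export
select_paf_strata <- function(pafs) {
  keep <- unlist(lapply(split(seq_len(nrow(pafs)),
                              paste(pafs$exposure, pafs$outcome, sep = "\r")),
                        function(idx) {
    if (any(pafs$sex[idx] == "total")) idx[pafs$sex[idx] == "total"] else idx
  }))
  out <- pafs[sort(keep), , drop = FALSE]
  attr(out, "application_mode") <- "total-preferred"
  out
}

#' Synthetic baseline DALY table derived from the published burden cells
#'
#' The national analysis publishes attributable fractions and attributable
#' DALYs, but not the baseline DALY totals it multiplied. This constructs a
#' synthetic stand-in by inverting the attribution step: for each published
#' burden cell, the baseline is the cell's DALY loss divided by the sum of
#' the full-precision attributable fractions of the strata applied to it
#' (total-sex when published, otherwise the published sex-specific strata,
#' assigned equal baselines). Attributing with these baselines reproduces
#' the published cells by construction — the table validates the
#' multiplication and aggregation path, it is not an observed burden table.
#'
#' @param cells Published burden cells, default [za_burden_cells()].
#' @param effects RR table, default [za_effect_table()].
#' @param prevalences Prevalence table, default [za_prevalence()].
#' @return A tibble `(exposure, outcome, sex, dalys)` of synthetic
#'   baselines.
#' @export
za_baseline_dalys_synthetic <- function(cells = za_burden_cells(),
                                        effects = za_effect_table(),
                                        prevalences = za_prevalence()) {
  pafs <- select_paf_strata(build_paf_table(prevalences, effects))
  out <- lapply(seq_len(nrow(cells)), function(i) {
    rows <- pafs[pafs$exposure == cells$exposure[i] &
                   pafs$outcome == cells$outcome[i], , drop = FALSE]
    if (nrow(rows) == 0) {
      stop_input(sprintf("no attributable fraction for burden cell (%s, %s)",
                         cells$exposure[i], cells$outcome[i]))
    }
    tibble::tibble(exposure = cells$exposure[i],
                   outcome = cells$outcome[i],
                   sex = rows$sex,
                   dalys = cells$daly_loss[i] / sum(rows$paf))
  })
  dplyr::bind_rows(out)
}
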