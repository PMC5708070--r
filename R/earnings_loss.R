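#' Economic parameters for burden valuation
#'
#' Container for the macro inputs of the costing stages. All values are in
#' nominal local currency (ZAR for the bundled South African tables).
#'
#' @param gdp_per_capita Per-capita GDP (currency per person-year); the
#'   value of one DALY under the human-capital approach.
#' @param gdp_total Total GDP (currency), used for share-of-GDP reporting.
#' @param median_monthly_earnings_base Median monthly earnings in the
#'   reference year, before price adjustment.
#' @param cpi_ratio Target-year price level over reference-year price level.
#' @param labour_force Labour-force size (persons).
#' @param exchange_rate Optional currency units per USD for report columns.
#' @return A list of class `econ_params`.
#' @export
econ_params <- function(gdp_per_capita,
                        gdp_total = NULL,
                        median_monthly_earnings_base = NULL,
                        cpi_ratio = 1,
                        labour_force = NULL,
                        exchange_rate = NULL) {
  check_non_negative(gdp_per_capita, "gdp_per_capita")
  for (nm in c("gdp_total", "median_monthly_earnings_base", "labour_force",
               "exchange_rate")) {
    v <- get(nm)
    if (!is.null(v)) check_positive(v, nm)
  }
  check_positive(cpi_ratio, "cpi_ratio")
  structure(list(gdp_per_capita = gdp_per_capita,
                 gdp_total = gdp_total,
                 median_monthly_earnings_base = median_monthly_earnings_base,
                 cpi_ratio = cpi_ratio,
                 labour_force = labour_force,
                 exchange_rate = exchange_rate),
            class = "econ_params")
}

#' Price-adjust earnings with a CPI ratio
#'
#' Rebases reference-year earnings to the analysis year by multiplying with
#' the consumer-price-index ratio. Full precision is kept; rounding to whole
#' currency units happens only in report formatting.
#'
#' @param base Earnings in reference-year currency.
#' @param cpi_ratio Target-year price level over reference-year level.
#' @return `base * cpi_ratio`.
#' @export
adjust_earnings <- function(base, cpi_ratio) {
  check_positive(base, "base")
  check_positive(cpi_ratio, "cpi_ratio")
  base * cpi_ratio
}

#' National productivity loss from a per-victim wage reduction
#'
#' Converts a proportional per-victim reduction in monthly earnings into a
#' national annual loss: the number of lifetime victims in the labour force
#' is `labour_force x prevalence`; each loses
#' `adjusted earnings x reduction` per month; the monthly total is the
#' product of the two and the annual total is twelve times that. Every
#' intermediate is kept at full precision — rounding the victim count or the
#' per-victim loss before multiplying shifts the total by millions — and the
#' rounded figures are provided separately for display only.
#'
#' @param prevalence Lifetime exposure prevalence in the (total-sex)
#'   population, in `[0, 1]`.
#' @param reduction Proportional reduction in monthly earnings, in `[0, 1)`
#'   (e.g. an estimate from [estimate_wage_effect()]).
#' @param econ An [econ_params()] with `median_monthly_earnings_base`,
#'   `cpi_ratio` and `labour_force` set; `gdp_total` enables the
#'   share-of-GDP column.
#' @param exposure Label carried through to the output.
#' @return A one-row tibble with unrounded `victims_in_labour_force`,
#'   `per_victim_monthly_loss`, `monthly_loss`, `annual_loss`,
#'   `share_of_gdp` (NA without `gdp_total`), and display-rounded
#'   `victims_display`, `per_victim_display`.
#' @export
productivity_loss <- function(prevalence, reduction, econ,
                              exposure = NA_character_) {
  check_prob(prevalence, "prevalence")
  if (!is.numeric(reduction) || reduction < 0 || reduction >= 1) {
    stop_input("`reduction` must lie in [0, 1)")
  }
  for (nm in c("median_monthly_earnings_base", "cpi_ratio", "labour_force")) {
    if (is.null(econ[[nm]])) {
      stop_input(sprintf("econ parameter `%s` is required for the earnings chain", nm))
    }
  }
  earnings <- adjust_earnings(econ$median_monthly_earnings_base, econ$cpi_ratio)
  victims <- econ$labour_force * prevalence
  per_victim <- earnings * reduction
  monthly <- victims * per_victim
  annual <- 12 * monthly
  tibble::tibble(
    exposure = exposure,
    victims_in_labour_force = victims,
    per_victim_monthly_loss = per_victim,
    monthly_loss = monthly,
    annual_loss = annual,
    share_of_gdp = if (is.null(econ$gdp_total)) NA_real_
                   else annual / econ$gdp_total,
    victims_display = round_half_up(victims),
    per_victim_display = round_half_up(per_victim)
  )
}
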