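#' Standard life table of expected years of life lost
#'
#' A loss function `L(a)` giving the expected years of healthy life lost for
#' a death at age `a`, anchored on a frontier (aspirational) life expectancy
#' in the style of the reference standard life tables used for
#' years-of-life-lost calculations. Ages must be strictly increasing and the
#' losses strictly decreasing.
#'
#' @param age Numeric vector of anchor ages (years).
#' @param yll Numeric vector of expected years of life lost at those ages.
#' @return A tibble of class `life_table`.
#' @export
life_table <- function(age, yll) {
  if (length(age) != length(yll) || length(age) < 1) {
    stop_input("`age` and `yll` must be equal-length, non-empty vectors")
  }
  if (is.unsorted(age, strictly = TRUE)) {
    stop_input("life-table ages must be strictly increasing")
  }
  if (length(yll) > 1 && any(diff(yll) >= 0)) {
    stop_input("years of life lost must be strictly decreasing with age")
  }
  check_non_negative(yll, "yll")
  structure(tibble::tibble(age = age, yll = yll),
            class = c("life_table", class(tibble::tibble())))
}

#' Years of life lost for a death at a given age
#'
#' Piecewise-linear interpolation of the life table between anchors; exact at
#' the anchors. Ages outside the tabulated range are an error rather than an
#' extrapolation.
#'
#' @param age Age(s) at death, years.
#' @param table A [life_table()].
#' @return Expected years of life lost.
#' @export
yll_at_age <- function(age, table) {
  check_cols(table, c("age", "yll"), "life table")
  if (any(age < min(table$age)) || any(age > max(table$age))) {
    stop_input(sprintf("age outside the life-table range [%g, %g]",
                       min(table$age), max(table$age)))
  }
  if (nrow(table) == 1) return(rep(table$yll, length(age)))
  approx(table$age, table$yll, xout = age, method = "linear")$y
}

#' Representative age of an age band
#'
#' The floored midpoint of an inclusive `[low, high]` band: bands 0-4, 5-9,
#' 10-14 and 15-17 map to ages 2, 7, 12 and 16. This floor convention
#' matches how burden studies take "the median age of the age group" for
#' child age bands.
#'
#' @param low,high Band endpoints in years (inclusive).
#' @return Integer representative age(s).
#' @export
band_representative_age <- function(low, high) floor((low + high) / 2)

#' Fatal DALYs from homicide counts and a life table
#'
#' Each age band contributes `deaths x L(a)` where `a` is the band's
#' representative (floored-midpoint) age and `L` the life-table loss
#' function; the total is the sum over bands. Additive over bands and
#' homogeneous of degree one in deaths; keep full precision and round only
#' when reporting.
#'
#' @param counts Tibble `(band_low, band_high, deaths)` of deaths per
#'   inclusive age band; bands must not overlap.
#' @param table A [life_table()].
#' @return Total years of life lost (numeric scalar, unrounded).
#' @export
fatal_dalys <- function(counts, table) {
  check_cols(counts, c("band_low", "band_high", "deaths"), "homicide counts")
  if (nrow(counts) == 0) {
    warning("no homicide counts supplied; fatal DALYs are 0", call. = FALSE)
    return(0)
  }
  check_non_negative(counts$deaths, "deaths")
  if (any(counts$deaths != round(counts$deaths))) {
    stop_input("`deaths` must be integer counts")
  }
  o <- order(counts$band_low)
  if (any(counts$band_low[o][-1] <= counts$band_high[o][-nrow(counts)])) {
    stop_input("homicide age bands overlap")
  }
  ages <- band_representative_age(counts$band_low, counts$band_high)
  sum(counts$deaths * yll_at_age(ages, table))
}

#' Attribute baseline DALYs to exposures via attributable fractions
#'
#' For each attributable-fraction record, multiplies the PAF by the matching
#' baseline DALY total, after removing from that baseline the contribution
#' of any cause categories mapped to the outcome in `exclusions`
#' (double-count removal: e.g. the self-harm and HIV/AIDS contributions are
#' subtracted from the drug-use baseline when those causes are attributed
#' separately). Sex-stratified records use sex-stratified baselines and are
#' then summed to exposure x outcome cells.
#'
#' Baselines match by `(outcome, sex)`; a baseline row may carry an
#' `exposure` column, in which case it applies only to that exposure
#' (needed when baselines are reverse-engineered per table cell). Negative
#' post-exclusion baselines are clipped to zero with a warning.
#'
#' @param pafs Tibble `(exposure, outcome, sex, paf)`, e.g. from
#'   [build_paf_table()].
#' @param baseline Tibble `(outcome, sex, dalys)` of baseline burden totals
#'   (age-15+ totals for nonfatal outcomes), optionally with an `exposure`
#'   column.
#' @param exclusions Named list: outcome (risk category) -> character vector
#'   of cause categories whose contributions are subtracted from its
#'   baseline.
#' @param contributions Tibble `(outcome, cause, sex, dalys)` quantifying
#'   each excluded cause's contribution within a risk category's baseline;
#'   required only when `exclusions` names causes for which the supplied
#'   baselines are not already net of the overlap.
#' @return A tibble `(exposure, outcome, sex, paf, baseline_dalys,
#'   daly_loss)`; see [aggregate_burden()] for exposure x outcome totals.
#' @export
attribute_dalys <- function(pafs, baseline, exclusions = NULL,
                            contributions = NULL) {
  check_cols(pafs, c("exposure", "outcome", "sex", "paf"), "pafs")
  check_cols(baseline, c("outcome", "sex", "dalys"), "baseline")
  if (nrow(pafs) == 0) {
    return(tibble::tibble(exposure = character(), outcome = character(),
                          sex = character(), paf = numeric(),
                          baseline_dalys = numeric(), daly_loss = numeric()))
  }
  base_key <- paste(baseline$outcome, baseline$sex)
  if ("exposure" %in% names(baseline)) {
    m <- match(paste(pafs$exposure, pafs$outcome, pafs$sex),
               paste(baseline$exposure, baseline$outcome, baseline$sex))
    # rows without exposure-specific baselines fall back to shared ones
    m2 <- match(paste(pafs$outcome, pafs$sex)[is.na(m)],
                base_key[is.na(baseline$exposure)])
    m[is.na(m)] <- which(is.na(baseline$exposure))[m2]
  } else {
    m <- match(paste(pafs$outcome, pafs$sex), base_key)
  }
  if (anyNA(m)) {
    bad <- unique(paste0("(", pafs$outcome[is.na(m)], ", ",
                         pafs$sex[is.na(m)], ")"))
    stop_input("no baseline DALY entry for cell(s): ",
               paste(bad, collapse = ", "))
  }
  base <- baseline$dalys[m]

  if (!is.null(exclusions) && length(exclusions)) {
    for (risk in names(exclusions)) {
      rows <- which(pafs$outcome == risk)
      if (!length(rows) || is.null(contributions)) next
      for (i in rows) {
        sub <- contributions$dalys[
          contributions$outcome == risk &
            contributions$cause %in% exclusions[[risk]] &
            contributions$sex == pafs$sex[i]]
        base[i] <- base[i] - sum(sub)
      }
    }
    if (any(base < 0)) {
      warning("post-exclusion baseline negative for ",
              sum(base < 0), " cell(s); clipped to zero", call. = FALSE)
      base <- pmax(base, 0)
    }
  }

  tibble::tibble(
    exposure = pafs$exposure,
    outcome = pafs$outcome,
    sex = pafs$sex,
    paf = pafs$paf,
    baseline_dalys = base,
    daly_loss = pafs$paf * base
  )
}

#' Aggregate attributed DALYs to exposure x outcome cells and totals
#'
#' Sums sex strata to exposure x outcome cells, then forms per-exposure
#' totals. When an exposure has a cell for an umbrella outcome (e.g. the
#' mental-disorders category) as well as cells for outcomes subsumed by it
#' (anxiety, depression), the subsumed cells are omitted from that
#' exposure's total — they are already counted inside the umbrella — while
#' still being reported individually. This is the tabulation-side face of
#' double-count removal.
#'
#' @param attributed Output of [attribute_dalys()].
#' @param overlap Named list: umbrella outcome -> outcomes it subsumes.
#'   Default: mental disorders subsume anxiety and depression.
#' @param gdp_per_capita Optional; when supplied, cells and totals gain an
#'   `economic_value` column via [monetise()].
#' @return A list with tibbles `cells` (exposure, outcome, daly_loss) and
#'   `totals` (exposure, daly_loss), plus `grand_total`.
#' @export
aggregate_burden <- function(attributed,
                             overlap = list(
                               serious_mental_illness = c("anxiety", "depression")),
                             gdp_per_capita = NULL) {
  cells <- attributed |>
    dplyr::count(exposure, outcome, wt = daly_loss, name = "daly_loss")
  totals_tab <- lapply(split(cells, cells$exposure), function(d) {
    drop <- character()
    for (umb in names(overlap)) {
      if (umb %in% d$outcome) drop <- c(drop, overlap[[umb]])
    }
    tibble::tibble(exposure = d$exposure[1],
                   daly_loss = sum(d$daly_loss[!d$outcome %in% drop]))
  })
  totals <- dplyr::bind_rows(totals_tab)
  if (!is.null(gdp_per_capita)) {
    # direct product, not monetise(): attributable cells may legitimately be
    # negative when an estimated RR falls below 1 (protective point estimate)
    cells$economic_value <- cells$daly_loss * gdp_per_capita
    totals$economic_value <- totals$daly_loss * gdp_per_capita
  }
  list(cells = cells, totals = totals, grand_total = sum(totals$daly_loss))
}

#' Monetise DALYs under the human-capital approach
#'
#' One DALY is valued at the country's per-capita GDP: a year of healthy
#' life lost is a year lost from average productive capacity.
#'
#' @param daly_loss Non-negative DALY total(s).
#' @param gdp_per_capita Non-negative per-capita GDP in currency units.
#' @return `daly_loss * gdp_per_capita`, in the same currency units.
#' @export
monetise <- function(daly_loss, gdp_per_capita) {
  check_non_negative(daly_loss, "daly_loss")
  check_non_negative(gdp_per_capita, "gdp_per_capita")
  daly_loss * gdp_per_capita
}

#' Consistency check of a printed burden table against a single GDP
#'
#' Verifies that one per-capita GDP explains every (DALY, economic value)
#' pair in a burden table whose values are rounded to a printing unit: the
#' implied GDP is the grand value/DALY quotient, and each printed value must
#' match `dalys x GDP` within half a printing unit (plus slack for the
#' DALY's own rounding).
#'
#' @param cells Tibble with a `daly_loss` column and a printed-value column.
#' @param gdp_per_capita The single rate to test against; when `NULL`
#'   (default) it is implied from the cells themselves by a
#'   regression-through-the-origin fit of value on DALYs, which is robust to
#'   the rounding noise of small cells.
#' @param value_col Name of the printed-value column (default
#'   `"value_million"`, the bundled tables' layout).
#' @param value_unit Currency units per printing unit (e.g. `1e6`).
#' @return A list: `gdp_per_capita` (implied or supplied), `max_abs_dev`
#'   (largest deviation in printing units), `max_rel_dev` (largest relative
#'   ratio deviation), `consistent` (logical).
#' @export
implied_gdp_check <- function(cells, gdp_per_capita = NULL,
                              value_col = "value_million",
                              value_unit = 1e6) {
  check_cols(cells, c("daly_loss", value_col), "burden cells")
  value <- as.numeric(cells[[value_col]])
  daly <- as.numeric(cells$daly_loss)
  gdp <- gdp_per_capita %||%
    (sum(daly * value) * value_unit / sum(daly^2))
  pred <- daly * gdp / value_unit
  dev <- abs(value - pred)
  # half a printing unit on the value, plus the value-equivalent of half a
  # DALY (DALY cells are themselves rounded to integers)
  tol <- 0.5 + 0.5 * gdp / value_unit
  list(gdp_per_capita = gdp,
       max_abs_dev = max(dev),
       max_rel_dev = max(dev / pred),
       consistent = all(dev <= tol))
}
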