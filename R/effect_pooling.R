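#' Adjust an unadjusted odds ratio by a published adjustment ratio
#'
#' Studies that report only a crude (unadjusted) odds ratio can be
#' approximately corrected for confounding by multiplying by the ratio of
#' adjusted to unadjusted ORs observed in comparable studies of the same
#' outcome.
#'
#' @param unadjusted_or Positive crude odds ratio.
#' @param adjustment_ratio Positive ratio (adjusted OR / unadjusted OR) from
#'   a comparable study; supplied per outcome in configuration, no defaults
#'   are invented.
#' @return The corrected odds ratio, `unadjusted_or * adjustment_ratio`.
#' @export
adjust_or <- function(unadjusted_or, adjustment_ratio) {
  check_positive(unadjusted_or, "unadjusted_or")
  check_positive(adjustment_ratio, "adjustment_ratio")
  unadjusted_or * adjustment_ratio
}

#' Convert an odds ratio to a relative risk (Zhang-Yu)
#'
#' `RR = OR / ((1 - p0) + p0 * OR)` where `p0` is the outcome risk among the
#' unexposed. As `p0 -> 0` (rare outcome) the RR approaches the OR; an OR of
#' 1 always maps to an RR of 1; for OR > 1 the RR lies in `(1, OR]`.
#'
#' @param or_value Positive odds ratio (vectorised).
#' @param p0 Unexposed outcome risk in `[0, 1)` (vectorised).
#' @return Relative risk(s).
#' @export
#' @examples
#' or_to_rr(2.0, 0.5)  # exposed odds 2 on unexposed risk 0.5 -> RR 4/3
or_to_rr <- function(or_value, p0) {
  check_positive(or_value, "or_value")
  if (!is.numeric(p0) || anyNA(p0) || any(p0 < 0) || any(p0 >= 1)) {
    stop_input("`p0` must lie in [0, 1): it is the unexposed outcome risk")
  }
  or_value / ((1 - p0) + p0 * or_value)
}

#' Build a study-effect table
#'
#' Canonical long-form container for study-level effect sizes: one row per
#' study x exposure x outcome x sex stratum with the reported measure (OR or
#' RR), its adjustment status, the study sample size, and (for OR rows) the
#' unexposed outcome risk `p0` needed for conversion.
#'
#' @param study_id,exposure,outcome,sex,measure,value,adjusted,n,p0 Vectors,
#'   recycled to a common length. `sex` must be one of `total`, `male`,
#'   `female`; `measure` one of `OR`, `RR`.
#' @return A tibble of class `study_effects`.
#' @export
study_effects <- function(study_id, exposure, outcome, sex = "total",
                          measure = "RR", value, adjusted = TRUE,
                          n, p0 = NA_real_) {
  tab <- tibble::tibble(study_id = study_id, exposure = exposure,
                        outcome = outcome, sex = sex, measure = measure,
                        value = value, adjusted = adjusted, n = n, p0 = p0)
  if (!all(tab$sex %in% c("total", "male", "female"))) {
    stop_input("`sex` must be one of total, male, female")
  }
  if (!all(tab$measure %in% c("OR", "RR"))) {
    stop_input("`measure` must be OR or RR")
  }
  check_positive(tab$value, "value")
  check_positive(tab$n, "n")
  class(tab) <- c("study_effects", class(tab))
  tab
}

#' Harmonise study effects to the RR scale
#'
#' Applies [adjust_or()] to unadjusted OR rows (using a per-outcome
#' adjustment-ratio table) and [or_to_rr()] to all OR rows, yielding a table
#' entirely on the RR scale and ready for pooling. In rare-outcome mode
#' `p0` is taken as 0 so each RR equals its OR; the mode used is recorded in
#' the `conversion` column.
#'
#' @param effects A [study_effects()] table.
#' @param p0_table Optional tibble `(outcome, sex, p0)` supplying unexposed
#'   risks for rows whose own `p0` is missing.
#' @param adjustment_ratios Optional tibble `(outcome, ratio)` of
#'   adjusted/unadjusted OR ratios applied to unadjusted OR rows.
#' @param rare_outcome If `TRUE`, treat all outcomes as rare (`p0 = 0`).
#' @return The table with `measure = "RR"` throughout and a `conversion`
#'   provenance column.
#' @export
harmonise_effects <- function(effects, p0_table = NULL,
                              adjustment_ratios = NULL,
                              rare_outcome = FALSE) {
  tab <- tibble::as_tibble(effects)
  tab$conversion <- ifelse(tab$measure == "RR", "reported-rr", NA_character_)
  is_or <- tab$measure == "OR"
  if (any(is_or & !tab$adjusted)) {
    if (is.null(adjustment_ratios)) {
      stop_input("unadjusted OR rows present but no `adjustment_ratios` table supplied")
    }
    idx <- which(is_or & !tab$adjusted)
    m <- match(tab$outcome[idx], adjustment_ratios$outcome)
    if (anyNA(m)) {
      stop_input("no adjustment ratio for outcome(s): ",
                 paste(unique(tab$outcome[idx][is.na(m)]), collapse = ", "))
    }
    tab$value[idx] <- adjust_or(tab$value[idx], adjustment_ratios$ratio[m])
    tab$adjusted[idx] <- TRUE
  }
  if (any(is_or)) {
    idx <- which(is_or)
    p0 <- tab$p0[idx]
    if (rare_outcome) {
      p0[] <- 0
      tab$conversion[idx] <- "or-rare-outcome"
    } else {
      need <- is.na(p0)
      if (any(need)) {
        if (is.null(p0_table)) {
          stop_input("OR rows lack `p0` and no `p0_table` was supplied; ",
                     "either provide unexposed risks or set rare_outcome = TRUE")
        }
        key <- paste(tab$outcome[idx][need], tab$sex[idx][need])
        m <- match(key, paste(p0_table$outcome, p0_table$sex))
        if (anyNA(m)) {
          stop_input("no baseline risk p0 for cell(s): ",
                     paste(unique(key[is.na(m)]), collapse = "; "))
        }
        p0[need] <- p0_table$p0[m]
      }
      tab$conversion[idx] <- "or-zhang-yu"
    }
    tab$value[idx] <- or_to_rr(tab$value[idx], p0)
    tab$p0[idx] <- p0
    tab$measure[idx] <- "RR"
  }
  tab
}

#' Pool relative risks with sample-size weighting
#'
#' Combines the studies of one exposure x outcome x sex cell into a single
#' RR using sample-size weights. The default pools on the log scale,
#' `exp(sum(n_i * log(rr_i)) / sum(n_i))`, which treats reciprocal effects
#' symmetrically; `scale = "linear"` pools the RRs themselves. Either way the
#' pooled value is a weighted mean, so it lies in the closed interval of the
#' input RRs.
#'
#' @param effects A table of RR-scale rows (e.g. from [harmonise_effects()])
#'   sharing one `(exposure, outcome, sex)` key.
#' @param scale `"log"` (default) or `"linear"`.
#' @return A one-row tibble with `exposure`, `outcome`, `sex`, `rr`,
#'   `total_n`, `k_studies` and `pooling_scale`.
#' @export
pool_rr <- function(effects, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (nrow(effects) == 0) stop_input("no effects to pool")
  if (!all(effects$measure == "RR")) {
    stop_input("all effects must be on the RR scale before pooling; ",
               "run harmonise_effects() first")
  }
  key <- unique(effects[, c("exposure", "outcome", "sex")])
  if (nrow(key) != 1) {
    stop_input("effects mix grouping keys; pool one (exposure, outcome, sex) ",
               "cell at a time or use pool_rr_table()")
  }
  w <- effects$n / sum(effects$n)
  rr <- if (scale == "log") exp(sum(w * log(effects$value)))
        else sum(w * effects$value)
  tibble::tibble(exposure = key$exposure, outcome = key$outcome,
                 sex = key$sex, rr = rr, total_n = sum(effects$n),
                 k_studies = nrow(effects), pooling_scale = scale)
}

#' Pool every (exposure, outcome, sex) cell of a harmonised table
#'
#' @inheritParams pool_rr
#' @return A tibble with one pooled row per cell.
#' @export
pool_rr_table <- function(effects, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  key <- paste(effects$exposure, effects$outcome, effects$sex, sep = "\r")
  dplyr::bind_rows(lapply(split(tibble::as_tibble(effects), key),
                          pool_rr, scale = scale))
}
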