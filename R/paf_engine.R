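#' Population attributable fraction
#'
#' The proportion of an outcome's population burden attributable to a binary
#' exposure, under Levin's formula
#' \deqn{PAF = \frac{p\,(RR-1)}{1 + p\,(RR-1)}}
#' with exposure prevalence `p` and relative risk `RR`. Equivalent to the
#' counterfactual contrast `(I - I0) / I` where the factual incidence is
#' `I = p r0 RR + (1 - p) r0` and the counterfactual (exposure removed)
#' incidence is `I0 = r0`, for any baseline risk `r0 > 0`.
#'
#' Monotone increasing in both `p` and `RR`; zero exactly when `p = 0` or
#' `RR = 1`; negative (a protective exposure) when `RR < 1`, which triggers
#' a warning since a protective violence exposure usually signals an input
#' error.
#'
#' @param p Exposure prevalence in `[0, 1]` (vectorised).
#' @param rr Positive relative risk (vectorised).
#' @return Attributable fraction(s) in `(-1, 1)`.
#' @export
#' @examples
#' paf(0.261, 1.18)  # 0.0449 to 4 d.p.
paf <- function(p, rr) {
  check_prob(p, "p")
  check_positive(rr, "rr")
  if (any(rr < 1)) {
    warning("rr < 1 yields a negative (protective) attributable fraction",
            call. = FALSE)
  }
  excess <- p * (rr - 1)
  excess / (1 + excess)
}

#' Build the attributable-fraction table
#'
#' Crosses pooled relative risks with exposure prevalences: one PAF record
#' per pooled RR cell, using the prevalence of the matching
#' `(exposure, sex)` stratum (sex-specific cells use sex-specific
#' prevalence; `total` cells use the total prevalence). Cells with no pooled
#' RR are simply absent from the output — they are never zero-filled,
#' mirroring reference tables that print "-" for inestimable cells.
#'
#' @param prevalences Tibble `(exposure, sex, p)` of lifetime exposure
#'   prevalences (proportions, not percentages).
#' @param pooled Tibble `(exposure, outcome, sex, rr)`, e.g. from
#'   [pool_rr_table()] or a published RR table.
#' @return A tibble `(exposure, outcome, sex, paf, rr_used, p_used)`.
#' @export
build_paf_table <- function(prevalences, pooled) {
  check_cols(prevalences, c("exposure", "sex", "p"), "prevalences")
  check_cols(pooled, c("exposure", "outcome", "sex", "rr"), "pooled")
  if (nrow(pooled) == 0) {
    return(tibble::tibble(exposure = character(), outcome = character(),
                          sex = character(), paf = numeric(),
                          rr_used = numeric(), p_used = numeric()))
  }
  m <- match(paste(pooled$exposure, pooled$sex),
             paste(prevalences$exposure, prevalences$sex))
  if (anyNA(m)) {
    bad <- unique(paste0("(", pooled$exposure[is.na(m)], ", ",
                         pooled$sex[is.na(m)], ")"))
    stop_input("no prevalence for cell(s): ", paste(bad, collapse = ", "))
  }
  p <- prevalences$p[m]
  tibble::tibble(
    exposure = pooled$exposure,
    outcome = pooled$outcome,
    sex = pooled$sex,
    paf = paf(p, pooled$rr),
    rr_used = pooled$rr,
    p_used = p
  )
}
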