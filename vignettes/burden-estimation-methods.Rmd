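---
title: "Methods: estimating the economic burden of violence against children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating the economic burden of violence against children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacburden)
```

## The estimation problem

`vacburden` implements a comparative-risk-assessment costing of childhood
violence at national scale. The chain has three stages:

1. **Effect harmonisation.** Study-level associations between a childhood
   exposure (sexual, physical or emotional violence, or neglect) and an
   adult outcome arrive as odds ratios or relative risks. Unadjusted ORs
   are corrected with published adjusted/unadjusted ratios, ORs are
   converted to RRs, and studies are pooled per exposure × outcome × sex
   cell with sample-size weights.
2. **Attributable burden.** Each pooled RR is combined with the lifetime
   exposure prevalence into a population attributable fraction (PAF),
   which is multiplied by that outcome's baseline burden in
   disability-adjusted life-years (DALYs). Fatal burden is added as
   homicide deaths valued through a standard life table. DALYs are
   monetised at one per-capita GDP per DALY (the human-capital approach).
3. **Earnings and services.** Selection-corrected proportional wage
   reductions are scaled to the national labour force, and provincial
   child-welfare spending is aggregated.

Every stage is also exercised against a synthetic cohort whose generating
parameters are known, so the estimators are validated by parameter
recovery rather than by fiat.

## Core formulas

**Attributable fraction.** For a binary exposure with prevalence $p$ and
relative risk $RR$,
$$\mathrm{PAF} = \frac{p\,(RR-1)}{1 + p\,(RR-1)},$$
identical to the counterfactual contrast $(I - I_0)/I$ with factual
incidence $I = p\,r_0\,RR + (1-p)\,r_0$ and counterfactual $I_0 = r_0$
for any baseline risk $r_0$; the package tests this identity to machine
precision. Sex-specific cells use sex-specific prevalence; both-sex cells
use total prevalence. An RR below 1 yields a negative (protective)
fraction, which is propagated with a warning rather than clipped — under a
true null the estimated fractions must be free to straddle zero or the
null-recovery tests would be biased.

**Odds-to-risk conversion.** With unexposed outcome risk $P_0$,
$$RR = \frac{OR}{(1-P_0) + P_0\,OR}.$$
The package checks this against an independent 2×2-table oracle (put the
unexposed on risk $P_0$, scale the odds by $OR$, read the exposed risk
back) over a grid of $(P_0, OR)$ at $10^{-12}$ relative tolerance. $P_0$
is a required per-(outcome, sex) input; a rare-outcome mode ($P_0 = 0$,
so $RR \equiv OR$) is available and recorded in the output's `conversion`
column. No baseline-risk defaults are invented.

**Pooling.** The default combines $k$ studies as
$\exp\!\big(\sum_i n_i \log rr_i / \sum_i n_i\big)$. Only "sample-size
weighting" is determined by the source methodology; the log scale is this
package's choice, for symmetry of reciprocal effects (a study reporting
$RR = 2$ and one reporting $RR = 1/2$ pool to 1). A linear-scale mode is
provided and the scale used is recorded in the output. Either way the
pooled value is a weighted mean, so it cannot leave the range of its
inputs.

**Fatal DALYs.** Deaths in age band $[l, h]$ are assigned the
representative age $\lfloor (l+h)/2 \rfloor$ — bands 0–4, 5–9, 10–14,
15–17 map to ages 2, 7, 12, 16 — and valued by piecewise-linear
interpolation of the standard life-table anchors (90.01, 85.02, 80.03,
76.04 years at those ages). The floor convention reproduces the reference
calculation exactly; ages outside the table are an error, not an
extrapolation.

**Monetisation.** One DALY is valued at the per-capita GDP. The bundled
rate is derived at run time from the bundled burden table (total economic
value ÷ total DALYs ≈ ZAR 73,061); the fatal-burden figure published
alongside it implies a slightly different rate (≈ 73,557), and the
table-implied value is the default because it is the one consistent with
the table the package reproduces.

## Double-count removal

Two mechanisms prevent the same DALY being attributed twice:

- **Baseline exclusion** (`attribute_dalys()`): when causes such as
  self-harm or HIV/AIDS are attributed in their own right, their
  contribution is subtracted from the baseline of an encompassing risk
  category (drug use, in the default map) before multiplication, via an
  explicit exclusion map and a contributions table. Only the documented
  example is encoded by default; the map is configuration, not inference.
- **Umbrella aggregation** (`aggregate_burden()`): when an exposure has a
  serious-mental-illness cell as well as anxiety or depression cells, the
  sub-outcome cells are omitted from that exposure's *total* (they are
  already inside the umbrella) while still being reported individually.
  This rule is exactly what reconciles the bundled burden table's printed
  cells with its printed per-exposure totals.

## The Heckman earnings stage

People who work are a non-random subset of the population, so a naive
regression of log wages on childhood exposures is biased. The two-stage
correction fits a probit participation model by maximum likelihood, then
regresses log wage on the exposure, confounders and the inverse Mills
ratio $\lambda(x) = \phi(x)/\Phi(x)$ evaluated at the first-stage linear
predictors. The proportional earnings reduction is $1 - e^{\beta}$ from
the exposure coefficient of the log-wage equation — the standard
earnings-equation convention, chosen because the source estimates are
reported only as percentage reductions. Standard errors are nonparametric
bootstrap (default 200 replicates; cluster bootstrap over a user-supplied
cluster column replaces design-based survey variance estimation, for
which no design parameters are available). Two-stage estimation (not
full-information maximum likelihood) is used, matching the method the
estimates describe. With the Mills column forced to zero the second stage
is ordinary least squares exactly, which the tests assert.

The participation equation needs at least one covariate excluded from the
wage equation (an exclusion restriction); which covariate plays that role
is the user's designation — the package warns when none is excluded and
identification rests on the Mills-ratio nonlinearity alone.

Binary-outcome effects use a log-link binomial GLM so the exponentiated
coefficient is an RR directly. Because the log link can leave the unit
interval, non-convergence triggers a fallback to a log-link Poisson model
with an HC0 sandwich variance — the standard robust-Poisson RR estimator —
with a warning naming the switch.

## The synthetic cohort generator

`generate_cohort()` draws a single cross-section emulating a Cape-Town
style youth panel: independent Bernoulli exposures at stated prevalences;
bernoulli/categorical/standard-normal confounders; binary outcomes under a
*log-risk* model (risk $= \exp(\alpha + \sum \beta x)$), so the generating
coefficients are log-RRs — chosen over a logistic model because the
downstream PAF machinery consumes RRs and the estimators fit log-link
models; log-normal wages with a proportional reduction
$(1-r)^{\text{exposure}}$ per violence type; and a probit participation
indicator whose latent error is bivariate-normal with the wage error at
correlation $\rho$. Wages are observed exactly when participation is 1.

Default study conditions: prevalences 0.261 (physical) and 0.126
(emotional); outcome RRs 1.55/1.35 (alcohol abuse) and 1.57/1.86
(anxiety) on the scale of the pooled national estimates; wage reductions
0.117 and 0.092; $\rho = 0.5$; wage residual SD 0.6 and probit
coefficients chosen to give roughly 55–60% participation, which is a
realistic labour-force share. Recovery checks run at $n = 50{,}000$,
large enough that 3-SE bands are a few percent of the truth while a full
suite run stays under a minute; the bootstrap in the recovery check uses
60 replicates (the function default is 200), which estimates the SE to
within ~10% — ample for a 3-SE band.

Validation rejects any specification whose worst-case log-risk exceeds 0
(binary covariates at their extremes, normal covariates at ±4 SD), and
generation re-checks realised risks and errors rather than truncating:
silent truncation would bias the very recovery tests the generator
exists to serve.

What the generator deliberately does **not** emulate: the longitudinal
five-wave structure and attrition of a real panel (a cross-section
suffices to exercise the estimators); correlation between violence types
(poly-victimisation), so recovery results say nothing about bias from
co-occurring exposures; and measurement error in self-reported exposure.
Passing recovery tests therefore demonstrate estimator correctness under
the stated model, not robustness to these real-data features.

## Reverse-derived baselines and reproduction accuracy

The national analysis publishes attributable fractions and attributable
DALYs but not the baseline DALY totals behind them. The bundled baseline
table (`za_baseline_dalys_synthetic()`) is therefore *synthetic*: each
published cell is divided by the full-precision attributable fraction(s)
applied to it. Full precision — rather than the printed, 2-decimal
fractions — is used because the pipeline recomputes fractions at full
precision, and dividing by a rounded 0.23 while multiplying by 0.2278
would drift cells by about 1%. Where only sex-specific fractions exist
for a cell, the cell is inverted against their sum with equal baselines
per stratum; the true allocation across sexes is not derivable from the
published table, and the stratum rule in force (`total-preferred`) is
recorded in the report's mode log. Attribution against these baselines
reproduces the published cells by construction; what it validates is the
multiplication, stratum-selection and aggregation path, not the
baselines themselves.

Two numerical facts cap attainable agreement with the published table and
are asserted at exactly that cap, no looser: the published sexual-violence
cells sum to 375,098 against a printed total of 375,097 (cells were
rounded independently of their total; the pipeline is tested to ±2
DALYs), and the million-Rand rounding of the value column means cells
under ZAR 300 m can deviate from a single GDP rate by up to ~0.24% even
though the totals row is consistent to 0.01% — the single-rate check is
therefore rounding-aware (each printed value within half a printing unit
of DALYs × rate).

## Rounding discipline in the earnings chain

The published earnings figures can only be reproduced with unrounded
intermediates: 21,084,500 × 0.261 victims times 3262 × 0.117 Rand gives
the printed monthly total ZAR 2,100,262,762 to the Rand, while the
product of the printed *rounded* intermediates (5,503,055 × 382) is
about ZAR 1.9 m away. `productivity_loss()` therefore carries full
precision end to end and exposes the display-rounded figures separately
(half-up rounding, since the reference figures round .5 up where R's
`round()` would not). The CPI ratio is configuration; the bundled value
is exactly 3262/3120, the ratio implied by the published endpoints.

## Scope boundaries and known limitations

- Witnessing family violence and exploitation are excluded from default
  totals (too few consequence studies); witnessing RRs are bundled and
  computed if a prevalence is supplied, but no witnessing prevalence row
  exists in the bundled survey table, so its printed fractions cannot be
  re-derived from bundled inputs.
- The age-15+ restriction on nonfatal baselines is a property of the
  supplied baseline table, not recomputed.
- No age-weighting, discounting, or uncertainty intervals on DALYs; no
  inverse-variance or random-effects meta-analysis or heterogeneity
  statistics — the pooling the package mirrors is sample-size weighted
  only.
- Exposures are treated as independent; poly-victimisation likely makes
  additive attribution an over-estimate.
- The single-year, prevalence-based snapshot does not project lifetime
  discounted earnings losses.

## A worked run

```{r, eval = FALSE}
report <- run_pipeline(pipeline_config(), verbose = TRUE)
print(report)
report$burden$totals
write_report(report, "vacburden-output")
```

The same computation is scripted in `scripts/acceptance.R`, and the
command-line wrapper `inst/cli/vacburden.R` exposes the stages
(`simulate`, `paf`, `burden`, `earnings`, `welfare`, `run-all`) for shell
use.
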