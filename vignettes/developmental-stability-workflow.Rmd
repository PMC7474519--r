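---
title: "Developmental stability and emergence production: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developmental stability and emergence production: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilat)
```

This vignette is the package's own account of the statistics it implements:
the asymmetry model and its ANOVA machinery, the biomass and export
accounting, the environmental-driver analyses, the synthetic-data generator
that stands in for field data, and the numerical conventions adopted where
the literature leaves a choice open.

## 1. Bilateral asymmetry as a developmental-stability signal

A bilaterally symmetric trait measured on the left (L) and right (R) side of
an individual carries three classically distinguished kinds of departure
from symmetry, identified from the distribution of the signed difference
d = R − L across individuals:

* **Fluctuating asymmetry (FA)** — d is normal with mean zero. Random
  developmental noise; the quantity of interest as a stress indicator.
* **Directional asymmetry (DA)** — d is normal with non-zero mean; one side
  is systematically larger.
* **Antisymmetry (AS)** — d is bimodal with mean zero; asymmetry is the
  rule but its direction is random.

Only FA is interpretable as developmental instability, so the workflow first
screens the alternatives out: a Shapiro–Wilk test on d rules antisymmetry
out when it does *not* reject (`screen_antisymmetry()`), and a two-sided
one-sample t-test of mean(d) = 0 rules directional asymmetry out when it
does not reject (`screen_directional()`). `fa_report()` combines both into a
verdict per trait-by-sex cell. A cell whose differences have zero variance
is labelled degenerate rather than classified — with no spread, none of the
tests are defined.

### Replicated measurements and the mixed ANOVA

Measurement error inflates apparent asymmetry, because |R − L| is small
relative to digitising error for most real traits. The classical remedy is
to measure each side M times (here M = 3 by default, in randomised order)
and partition the variance with a two-way mixed ANOVA: side (fixed),
individual (random), their interaction, and the replicate-level residual.
For a balanced design (n individuals × 2 sides × M replicates) the sums of
squares have the closed form implemented in `two_way_mixed_anova()`:

$$SS_{side} = nM\sum_s(\bar y_s - \bar y)^2,\qquad
  SS_{ind} = 2M\sum_i(\bar y_i - \bar y)^2,$$
$$SS_{S\times I} = M\sum_{s,i}(\bar y_{si} - \bar y_s - \bar y_i + \bar y)^2,
  \qquad SS_{err} = \sum_{s,i,m}(y_{sim} - \bar y_{si})^2.$$

The interaction stratum carries the true side-by-individual signal — i.e.
asymmetry — while the residual carries replicate error, with expectations
$E[MS_{err}] = \sigma_{me}^2$ and
$E[MS_{S\times I}] = \sigma_{me}^2 + M\sigma_i^2$, where $\sigma_i^2$ is the
interaction variance component. F-ratios follow the mixed-model convention:
side and individual are tested over the interaction mean square, the
interaction over the residual. The denominators are recorded in the output
so alternative conventions can be audited. Unbalanced individuals are
excluded from the ANOVA (and flagged on input) but retained for
body-length analyses; the closed forms above assume balance and the
package refuses to run them otherwise.

### The index suite

* **FA1** = mean |d|. Transparent, but contains measurement error.
* **FA4a** = 0.798 × SD(d), with the (n − 1)-denominator sample SD. For
  normal zero-mean d, E|d| = σ√(2/π) ≈ 0.798 σ, so FA4a estimates the same
  quantity as FA1 with more statistical power — and the same error
  contamination.
* **FA10a** = 0.798 √(2 σ̂ᵢ²) with
  σ̂ᵢ² = max(0, (MS_{S×I} − MS_{err}) / M): the error-corrected index. Under
  the package's generative model (below) the side split makes
  var(R − L) = 2σᵢ², so FA10a returns to the FA1/FA4a scale but with
  replicate error partitioned out.
* **ME3** = 100 × MS_{err} / MS_{S×I}: replicate error as a percentage of
  the interaction signal it contaminates.

**The divisor M.** Some published accounts print the component as
σᵢ² = MS_{S×I} − MS_{err}, without the divisor. The divisor form is the
standard variance-component estimator for an M-replicate design — it is what
makes $E[\hat\sigma_i^2] = \sigma_i^2$ — and it is the form under which the
published index values shipped in `reference_fa_table()` reproduce from
their own printed mean squares (verified by `reproduce_reference()` and the
test suite). `fa10a(..., use_printed_formula = TRUE)` exposes the
divisor-free variant for comparison with sources that use it. A negative
component estimate (possible when the true σᵢ² is near zero) clamps to zero
with a warning, so FA10a is never negative or NaN.

**Collapsing replicates.** Signed differences use the mean of the M
replicates per side. How triplicates are collapsed is rarely stated in the
literature; replicate means are the natural companion to an analysis that
handles measurement error in the ANOVA's interaction stratum, which is where
the error-corrected index comes from.

**Reproduction at printed precision.** `reproduce_reference()` recomputes
every desk-scale published quantity from its printed inputs and compares at
the precision those numbers were printed with: half a unit in the last
printed place, widened for mean-square-derived quantities by the rounding
the 3-significant-figure inputs themselves carry (an FA10a printed as 0.012
from inputs printed as 4.25E−4 and 5.67E−5 is reproducible only to ~5×10⁻⁴).
One published cell is internally inconsistent — the male forewing-area ME3
prints 16.4 where its own printed mean squares give ≈ 7.5 — and is carried
as a flagged known discrepancy, not a failure.

## 2. Biomass, production and export

Individual lengths convert to mass through the power allometry
m = a·lengthᵇ (mg ash-free dry mass; `length_to_mass()`). The coefficients
are taxon-specific and deliberately have **no package defaults**: they are
required configuration, because baking in one taxon's published coefficients
would silently misstate every other taxon's biomass. `monthly_series()`
accumulates mass/area by calendar month and compartment (benthic cores,
default 0.006 m²; emergence trap, default 2 m²), reporting unsampled months
as missing rather than zero.

Annual secondary production uses the production-to-biomass shortcut
P = B × (P/B) (`annual_production()`), appropriate when cohorts cannot be
followed; B is the mean of the year's monthly benthic biomass. The export
ratio E/P (`ep_ratio()`, `production_summary()`) divides the annual
emergence total — the sum of the year's monthly emergence biomass, only for
years with complete 12-month coverage — by P. E/P is computed from annual
totals, not averaged monthly ratios; that is the arithmetic under which the
published example values (38.57% and 19.78% from E = 9.14, P = 23.70 and
E = 5.99, P = 30.28 mg AFDM m⁻² y⁻¹) reproduce exactly.

## 3. Environmental drivers

`trailing_window_mean()` averages daily precipitation over the
`window_days` days **strictly before** each collection date
(start-inclusive, end-exclusive). The default window of 159 days is the
median egg-to-adult development time reported for a confamilial mayfly, so
the window mean summarises the rainfall an individual experienced as a
nymph; the endpoint convention is rarely stated in the literature, and
end-exclusive is adopted here because the collection day itself cannot have
influenced development that is already complete. Gaps in coverage are an
error listing the missing dates, never silently skipped.

Correlations delegate to `stats::cor.test()`: Pearson for
precipitation–discharge, Spearman (midranks, exact null distribution for
n ≤ 10 without ties, t-approximation otherwise) for body length against the
window mean, per sex and combined.

`collinearity_screen()` prepares a predictor table in two stages: pairwise
|r| > 0.60 drops the later predictor of each offending pair (input order, so
the screening is deterministic and auditable), then predictors with variance
inflation factor above 10 are removed one at a time, worst first.
`aicc_forward_selection()` then runs greedy forward selection under
AICc = n·ln(RSS/n) + 2k + 2k(k+1)/(n−k−1), with k counting the intercept
and the error variance (so the null model has k = 2). Steps add whichever
predictor most lowers AICc and stop when none lowers it; exact ties break
toward fewer predictors, then input order. All models evaluated during the
search form the candidate set; Akaike weights are computed over it, the
confidence subset is ΔAICc < 2, and model-averaged coefficients are
subset-renormalised weighted means with zeros where a model omits a term.

**"No supported model."** The fit is reported as unsupported when the
intercept-only model lies within ΔAICc = 2 of the best candidate: no
predictor model is then convincingly better than nothing. This is a
deliberate design choice. Greedy AIC-family selection admits a spurious
predictor with roughly 12–16% probability per candidate (the well-known
asymptotic false-inclusion rate), so "the final forward-selection model has
predictors" is a weak null diagnostic; "something beats the null by more
than the equivalence band" is the statement practitioners mean when they
report no support for any model, and it is the definition used throughout
the package and its tests. Even so, with several screened-but-correlated
monthly predictors and two years of monthly records, spurious support
still arises in roughly a quarter of null simulations — model selection on
24 observations is noisy, and the package's tests document that rate
rather than hide it.

## 4. What the synthetic-data module emulates

`simulate_bilateral()` draws, per individual, a latent size
T ~ N(μ_T, σ_T²) and a signed asymmetry d from the active regime (FA, DA,
AS, or NONE), then splits it symmetrically: L = T − d/2, R = T + d/2. The
split is the reason every estimator's target is analytically known:
var(R − L) = σ_d² exactly and the interaction variance component is
σ_d²/2, so FA4a and FA10a both target 0.798 σ_d. Each replicate observation
adds independent N(0, σ_me²) error — additive, homoscedastic, independent
across replicates, exactly the error model the two-way ANOVA assumes.
Draws that would produce non-positive measurements are redrawn with a
logged count.

`simulate_field()` emulates a two-year tropical monitoring design starting
January 2002: daily rainfall as a truncated two-bump seasonal mean curve
(dry-season baseline 5.5 mm/day; bumps of +12 and +10 mm/day centred on
day-of-year 182 and 335, widths 40 and 35 days — wet peaks in June–July and
November–December exceeding 400 mm/month against a February–April dry
season, ~4000 mm/year) times mean-one lognormal daily noise (σ_log = 0.9),
so values are non-negative and monthly summaries are reproducible from the
daily series. Monthly physicochemistry (discharge, temperature, pH,
conductivity, NO₃-N, NH₄-N, SRP) shares part of the seasonal rainfall
signal, which gives the realistic inter-correlations a collinearity screen
exists for; discharge tracks monthly rainfall with r ≈ 0.6–0.7. Monthly
benthic biomass is lognormal around 1.2 mg AFDM/m² with three randomly
placed peak months per year (×4), while emergence biomass is near-constant
(N(0.63, 0.12²) truncated at zero) — irregular benthic peaks over a flat
emergence series, with **no environmental driver of emergence**, so the
model-selection null behaviour is testable. Adult body length is
β₀ + β₁·(159-day trailing rainfall mean) + N(0, σ²); the defaults
β₀ = 8.5 mm, β₁ = −0.25 mm/(mm day⁻¹), σ = 0.45 mm give a Spearman ρ near
−0.5, the effect size the workflow is meant to detect, while parameter-
recovery tests use a steeper-signal configuration (β₁ = −0.02 with σ = 0.02
and n = 200) where the direction and significance must be recovered
essentially always.

What the generator does **not** emulate: real rainfall autocorrelation and
storm clustering, true allometry coefficients for any taxon, size-dependent
emergence phenology, spatial structure, or observation error in the biomass
series. Passing tests therefore demonstrate that the estimators recover the
parameters of their assumed model — not that any particular field system
satisfies that model.

## 5. Problem sizes and numerical conventions

The test suite runs at sizes chosen to make Monte-Carlo bands tight enough
to be informative while keeping a full run in minutes: 500 simulated
datasets (n = 100 individuals, M = 3) for index recovery at three
measurement-error levels; 2000 replicates (n = 30) for the screens' type-I
error, asserted within [0.03, 0.07] at α = 0.05; 200 seeded field
simulations for Spearman recovery and null calibration; 500 for the
model-selection null rate; 50 random balanced designs (n ≤ 10, M ≤ 4) for
the ANOVA-against-naive-loop oracle at 10⁻¹⁰ relative tolerance, plus an
independent cross-check against `stats::aov()`.

Other conventions: all randomness flows through per-spec seeds and
generators are bit-reproducible given (spec, seed); CSV dialects are
comma-separated UTF-8 with ISO-8601 dates; measurement precision (0.01 mm
or mm²) is metadata, not enforced rounding, because analyses use raw
values; validation never drops data silently (excluded rows are counted in
warnings and attributes); and ledger-style comparisons against printed
values round half-up, matching how tables are typeset.

## 6. Known limitations

* The balanced closed-form ANOVA is exact but refuses unbalanced cells; a
  REML mixed-model route would use partially measured individuals at the
  cost of closed-form auditability.
* P/B production inherits the full uncertainty of the assumed turnover
  ratio; the package propagates none of it.
* FA indices are not size-corrected (no FA2/FA3/FA8); between-trait
  comparisons rely on the FA1/mean percentage only.
* AICc selection on ~24 monthly observations has limited power and a
  non-trivial false-support rate, as quantified above; conclusions about
  environmental drivers at this design size are necessarily weak.
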