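---
title: "Urban organic carbon accounting: model, uncertainty, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Urban organic carbon accounting: model, uncertainty, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbancarbon)
```

## The accounting model

Urban land stores organic carbon in two natural pools — the vegetation of
green spaces and the soil column — and two anthropogenic ones — human
bodies and the wood bound up in buildings and furniture. `urbancarbon`
implements a province-level bookkeeping model of these four pools.

With `Area` the urban land area, `α` the green-space fraction of it, and
`D` carbon densities (kg C m⁻², soils integrated to 100 cm):

* **Vegetation** `C_veg = Area · α · D_green`
* **Soil** `C_soil = Area · (α · D_sgreen + (1 − α) · D_simp)`, taking
  literally the assumption that all urban soil lies beneath either green
  space or impervious cover. No separate category for water bodies or bare
  ground is modelled; if such covers matter for a data set they must be
  folded into the impervious class.
* **Humans** `C_hum = P_urban · Weight_ave · f₁ · f₂` with a 60 kg average
  body weight, a 0.3 dry-organic-matter fraction and a 0.5 carbon fraction
  of dry matter — about 9 kg C per person, which is why this pool is
  essentially negligible (~1% nationally).
* **Buildings** construction wood
  `(A_resid · f₃ + (A_total − A_resid) · f₅) · f₄` plus furniture wood
  `N_set · N_household · f₆ · (f₇·f₈ + f₉·f₁₀) · f₄`, both converted to
  carbon with `f₂`. Wood-use rates are 0.045 m³ m⁻² for residential and
  0.055 m³ m⁻² for commercial floor area, the bulk density of wood is
  0.4 t m⁻³, and a composite furniture set averages 20 pieces, 80% wood
  (0.067 m³ each) and 20% steel-framed (0.026 m³ of wood each).

Two conventions deserve a note because the source statistics do not force
them. Commercial floor area is defined as total minus residential floor
area, since yearbooks tabulate only those two quantities but the two wood-use
rates require the split. Furniture wood volume is converted to mass with the
same bulk density `f₄` as construction wood, because furniture factors are
given as volumes per piece and only one bulk density is available.

Internally every stock is carried in kg C; reporting is in Tg C (10⁹ kg) and
densities in kg C m⁻². Conversions live in one place (`kg_to_tg()` and the
constants beside it), so the kg and Tg computation paths agree to 10⁻¹⁰
relative tolerance. The green-space fraction is stored as a fraction in
[0, 1]; yearbook percentages must be divided by 100 at ingest. Provinces
with zero total stock are legal in aggregation but are reported with zero
pool fractions and a `zero_total` flag, and provinces with non-positive
area are excluded from density and regression computations.

All coefficients are overridable through `model_constants()` or a YAML/JSON
file (`read_constants()`), with the literature defaults above.

## Monte Carlo uncertainty

Most inputs to the model come from sparse surveys or census tables whose
dispersion is unknown; they are assigned a normal distribution with mean at
the point estimate and a coefficient of variation `β = 0.15`. Soil organic
carbon is characteristically right-skewed, so the two soil densities are
instead given log-normal distributions whose *arithmetic* mean and SD match
the point estimate and its dispersion — `D_sgreen` with CV `β` and `D_simp`
with its database-derived absolute SD (`sd_simp`). Which of the two soil
variables should use `β` is not determined by the source statistics;
`province_distributions()` uses `β` for the green-space soil density and the
supplied absolute SD for the impervious one, and both choices are
per-variable overridable by editing the returned specification.

Mean matching is solved in closed form: `σ² = ln(1 + sd²/mean²)` and
`μ = ln(mean) − σ²/2`, equivalently an additive log-scale correction
`k = −σ²/2` relative to the naive `ln(mean)`. A numerical-optimization mode
(`lognormal_params(..., method = "optimize")`) recovers the same `k` by
minimizing the mean mismatch; it exists as a fidelity cross-check of the
closed form, which is cheaper and deterministic and is the default.

`mc_province()` draws 10,000 independent joint samples per province by
default, pushes each through the four-pool model, and reports each pool and
the total as mean ± 1.96 × SD of the Monte Carlo distribution. The
"±1.96 × standard error" phrasing conventional in inventory reporting is
interpreted here as the SD of the simulated distribution of the stock, not
the standard error of its mean — at 10,000 draws the latter would be ~100×
smaller and could not produce the tens-of-Tg intervals such inventories
report. Residential and commercial floor areas are sampled as separate
variables so the residential ≤ total ordering survives reconstruction.

Numerical details:

* Normal draws are clipped at zero (the inputs are physically
  non-negative). At CV 0.15 the clip probability is ~10⁻¹¹ per draw, so the
  induced bias is far below Monte Carlo noise; clip counts are returned so
  heavier-tailed configurations can be audited. Green-fraction draws are
  additionally capped at 1.
* Seeding is hierarchical: one master seed spawns a deterministic
  per-province substream (`seed + 1000003·i mod 2³¹−1`), so adding or
  removing a province never changes another province's draws, and identical
  seeds give bit-identical summaries.
* Provinces are combined (`combine_provinces()`) by summing draws
  index-wise, i.e. assuming independence across provinces; the combined SD
  is the Monte Carlo realization of `√Σsᵢ²`. Within a province, variables
  are drawn independently — no covariance modelling is attempted, which
  will understate uncertainty if, say, areas and populations err together.

## One-at-a-time sensitivity

`sensitivity_table()` multiplies one variable at a time by 1.10 in every
province simultaneously (model coefficients are global and scaled once),
recomputes the national point-estimate total, and reports
`100 × (C′ − C)/C`. The point-estimate model is multilinear, so a variable
entering only as a linear factor of pools with combined national share `s`
responds by exactly `10·s` percent — the closed-form oracle the test suite
checks to 10⁻⁹ — and no response can exceed 10%.

The registry holds 21 variables: the 11 province-level inputs (with the
impervious fraction and the commercial floor area registered as quantities
independent of their complements) and 10 global coefficients. Two design
choices were genuinely open:

* **Fraction coupling.** The impervious fraction equals `1 − α` at
  baseline, but it is perturbed *without* re-deriving `α`, and vice versa —
  the two enter the registry as independent measurement quantities, which
  is why their responses are not negatives of each other. The land-cover
  tradeoff interpretation (greening consumes impervious area, which can
  make the response negative wherever impervious soil is carbon-richer than
  green space plus its soil) is available as
  `perturb_variable(..., couple_fractions = TRUE)`.
* **`f₇`/`f₉`.** The wood- and steel-furniture fractions are complementary,
  so perturbing `f₇` re-derives `f₉ = 1 − f₇`; with the default
  `f₈ > f₁₀` the response is positive, and it flips sign if a configuration
  makes steel furniture the wood-richer class.

Sensitivity runs on point estimates, not Monte Carlo draws, matching the
deterministic framing of a "10% increase".

## Aggregation, regression, extrapolation

`aggregate_provinces()` sums stocks over regions and the nation, derives
densities as stock over area and pool fractions as pool sums over totals,
and — when Monte Carlo results are supplied — obtains regional and national
half-widths by draw-summation. Aggregation is associative: provinces →
regions → nation equals provinces → nation exactly.

`fit_storage_area()` regresses provincial total stock (Tg C) on urban area
in units of 1,000 km², so the slope is the *specific urban carbon storage*
(Tg C per 1,000 km² of urban land). OLS with intercept is the default; a
through-origin option exists because the specific-storage phrasing is
ratio-like and either convention is defensible for a quantity that must
vanish at zero area. `extrapolate_global()` multiplies a slope by
bracketing global urban-area estimates, and `context_ratios()` situates an
urban stock against a national terrestrial stock and land area (defaults:
77.4 Pg C and 9.60 × 10⁶ km², the cited values for China, both
overridable); its density ratio is identically the ratio of the stock and
area shares.

## The synthetic generator

No provincial input table can be redistributed with the package — the
underlying yearbook compilations are not openly licensed — so
`generate_provinces()` builds tables with the *structure* the analysis
assumes: 31 provinces in six regions (5/3/7/6/5/5), urban areas drawn
log-normally (log-scale SD 1.0, spanning roughly two orders of magnitude)
and rescaled to sum to 33,697 km², green fractions uniform on 0.31 ± 0.14,
vegetation density 0.4–2.5 kg C m⁻² and soil densities of a few to
~16 kg C m⁻² drawn log-normally within their ranges (clamped), so
provincial urban carbon densities land in the observed 8.6–28.9 kg C m⁻²
envelope. Population scales with area through an urban density of
8,000–30,000 persons km⁻², floor area through 30 m² per capita (split
50–80% residential), households through 3 persons per household, and
furniture through 0.5–2 sets per household — early-2000s Chinese urban
magnitudes. The generator records its own per-province pool bookkeeping,
computed by direct arithmetic, as a `"truth"` attribute; the pipeline must
reproduce it exactly (closed-loop test).

What the generator does *not* emulate: spatial correlation between
neighbouring provinces, region-specific density regimes (cold-climate soils
carrying systematically more carbon), reporting artifacts of real
yearbooks, or covariance between densities and urbanization level. Tests
passing on synthetic tables therefore demonstrate the correctness of the
accounting, propagation and aggregation machinery — not that any particular
real-world estimate is right.

`calibrate_national()` rescales the inputs each pool is linear in
(`d_green`; the soil densities; `pop_urban`; floor areas with `n_set`) so
the national point-estimate run hits a target total and pool partitioning
exactly — closed form, no optimization, since stocks are linear in the
scale factors. The default targets are the published 2006 national
aggregates for China (577.0 Tg C partitioned 7.3/56.1/1.0/35.6% over
33,697 km², hence 17.1 kg C m⁻²), giving a fixture on which published
identities — e.g. the 6.3% response of the total to a 10% area increase,
which is just 10 × the combined vegetation-and-soil share — can be
recomputed from scratch.

## Problem sizes and runtime choices

The test suite runs Monte Carlo at 2,000–10,000 draws on 1–3 province
fixtures and the distributional checks at 10⁵ draws; the full suite
completes in a few seconds. Full national runs (31 provinces × 10,000
draws) take a few seconds as well, since draws are pushed through the
vectorized pool functions in bulk. Law-of-large-numbers checks use 10⁴
generated provinces.

## Known limitations

* Pools omitted by design: pets, books, food stocks (all ≪1% of the
  human/building pools), and any green-space typing (urban forest vs
  grassland) — the input statistics do not distinguish them.
* No covariance between inputs, within or across provinces; uncertainty is
  therefore a lower bound wherever inputs co-err.
* The regression and extrapolation assume the storage–area relationship is
  linear across scales and transferable across regions; the through-origin
  and intercept variants bracket that assumption but do not test it.
* Published regional tables are shipped as cited constants
  (`china_region_table()`, `china_pool_fractions()`) for consistency checks
  only; the package does not recompute them from primary yearbook data.
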