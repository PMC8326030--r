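---
title: "Modelling pathways to 5-a-day: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pathways to 5-a-day: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiveaday)
```

This vignette is the package's own account of its model: what is being
computed, under which assumptions, which parameters matter, and where the
design was genuinely open and a choice had to be made.

## The diet model

A diet is a national-average intake vector (g/person/day) over a table of
compositionally distinct food groups, each carrying an energy density
(kcal/g), a price (GBP/kg) and supply-weighted greenhouse-gas (kg CO₂eq/kg)
and blue-water (L/kg) factors. Blue water is ground and surface water only;
rain-fed production does not count, which is why domestically grown produce
tends to carry lower factors. Where a food is supplied from several
origins, its factor is the share-weighted mean of the origin factors
(`weighted_footprint()`), with `GLOBAL` rows as fallback where no
country-specific estimate exists.

Counting toward the 400-g target follows the national recommendation:
fruit and vegetables including legumes; fruit juice and potatoes excluded
(they remain in the diet and keep their cost and footprints — they simply
do not count); legumes capped at one 80-g portion. The cap is a property
of *counting*, not of the food: a diet may contain 150 g of legumes, of
which 80 g count. Fruit and vegetables inside composite processed foods
are not counted either; composites sit in the `other` category.

One modelling question the counting rules leave open is whether baked
beans — consumed in the UK as a dish of white beans, tomatoes and water —
count fully as legume toward the cap. The package counts them fully; a
partial attribution would require a recipe decomposition that the
food-group level of aggregation cannot support.

## The pathway optimization

Each pathway is characterised by its eligible set: counting-eligible foods
in the increase categories (fruit+vegetables+legumes for `FV_*`,
vegetables+legumes for `VEG_*`), intersected with UK-capable varieties for
`*_UK`, and excluding foods with zero baseline intake (a proportional
increase leaves zero at zero, and a relative deviation from zero is
undefined). The increase is proportionate to current consumption: all
eligible intakes are multiplied by one scale factor *s*. The counted total
is piecewise linear in *s* because of the legume cap, so *s* solves in
closed form on each linear piece; if the cap makes the target unreachable
(only legumes eligible), the pathway is reported infeasible with the gap.

Substitution is per kilocalorie: the energy added by extra fruit is
removed from the sweet-snack pool, the energy added by extra vegetables
and legumes from the meat pool (red, processed and poultry together).
Within a pool the published rule does not say how the reduction is
allocated across foods; the package reduces every pool food proportionally
to its baseline energy contribution. This is deterministic and scale-free,
reduces to the published behaviour whenever the pool suffices, and treats
poultry exactly like the rest of the meat pool (the published models do
not state a poultry-specific split either). Pool foods floor at zero; if a
pool is exhausted the residual energy imbalance passes to the remaining
"free" foods.

The free-food stage is the linear program: minimise the total relative
deviation Σ|xᵢ−bᵢ|/bᵢ over foods not directly modified (everything except
fruit, vegetables, legumes, sweet snacks and meat), subject to total
dietary energy equal to baseline and xᵢ ≥ 0. With the pool reductions
fixed as equalities — which also makes the optimum unique and
deterministic — only one equality constraint remains. Its exact optimum
has a closed form: one unit of relative deviation on food *i* turns over
eᵢ·bᵢ kcal, so an optimal solution concentrates the adjustment on foods in
decreasing order of eᵢ·bᵢ, each bounded below by zero (a fractional-
knapsack exchange argument). The package implements that exact solve
directly rather than calling a numerical LP solver, and the test suite
checks it against a brute-force grid search on small instances. The free
foods are allowed to move in either direction, penalised symmetrically;
with the pools as equalities only energy removal ever arises in practice.
Constraint residuals are held to 1e-9; energy conservation and target
attainment are asserted to 1e-6 relative in the tests.

## The life-table health model

Health impacts use an annual-cycle life table per sex. Two runs differ
only in mortality: the baseline all-cause schedule m(a), held constant
over follow-up, and the impacted schedule

m′(a, t) = m(a) − Σₒ crₒ(a) · (1 − RRₒ(t)),

where crₒ is the cause-specific mortality rate of outcome *o* and RRₒ(t)
the combined, lagged relative risk. Each exposure–response pair is
log-linear, RR(Δ) = RR^(Δ/unit) with the sign convention that moving in
the stated beneficial direction is protective; risks acting on the same
outcome multiply (equivalently, their log-risks add, which is why the lag
is applied on the log scale: RRₒ(t) = exp(log RRₒ · w(t)) preserves
multiplicativity). Dietary exposure changes are category aggregates of the
optimized diet, with legumes separate from other vegetables and poultry
excluded for lack of relative-risk data. The diet is adopted instantly at
t = 0.

The published lag description fixes the endpoints — cardiometabolic
effects complete by 10 y; cancer effects zero before 10 y and complete by
30 y, following normal-CDF S-curves — but not the normal's parameters. The
package sets the mean at the midpoint of the ramp and the SD to
ramp/5.164, so the weight is ≈0.005 at the ramp start and ≈0.995 at its
end, then clamps to exactly zero before the cancer ramp begins. Weights
are evaluated at mid-year (t − ½ in year t). These parameters are exposed
through `lag_profile()`.

Hazards convert to annual death probabilities by q = 1 − exp(−m); deaths
receive half a year of person-time. The difference from the alternative
m/(1+m/2) conversion is far below every tolerance used here. Two distinct
quantities are reported, matching their different definitions:

* **life-years gained**: the current population aged forward (no births,
  no migration) under baseline versus impacted rates, person-year
  difference by calendar year, over a 120-year horizon so all cohorts
  close out;
* **change in life expectancy at birth**: a birth cohort entering at
  t = 0, experiencing the time-varying impacted rates along its diagonal
  (age a in year a), expected life-years divided by the starting cohort
  size, per sex.

How the published combined life expectancy weights the sexes is not
stated; the package reports both a birth-ratio weighting (105 male : 100
female, configurable) and the simple mean, using the former as the
headline. The fruit-and-vegetable attribution share reruns the model with
the meat deltas zeroed and reports the ratio of life-expectancy changes;
it is flagged `NA` when the full change is zero. Sensitivity bounds rerun
with every relative risk at its lower (stronger protection) or upper CI
bound; the packaged table applies lung and esophageal cancer risks to
fruit only, exactly as tabulated, without extrapolating them to
vegetables.

## The synthetic world

The generator emulates the *structure* of the restricted inputs (dietary
survey aggregates, trade shares, national statistics mortality), not their
microdata. Its defaults are the stated world:

* 48 fruit, 64 vegetable (including legume) and 153 other food groups;
  baseline aggregates calibrated exactly (to floating point) to 88 g
  fruit, 140 g vegetables, 1744 kcal, £6.78, 6.2 kg CO₂eq and 611.4 L per
  person per day. The published text rounds the water footprint to 611 L;
  the tabulated baseline value 611.4 is used.
* the major named varieties pinned at their published intakes (bananas
  23.84 g — 27% of all fruit — tomatoes 24.93 g, baked beans 15.47 g, …),
  giving the heavy-tailed intake distribution real survey data show;
  unnamed groups draw log-normal intakes rescaled to the category
  remainder.
* energy densities uniform in category-plausible ranges (fruit 0.3–0.9,
  vegetables 0.2–0.8, sweet snacks 3.5–5.5, meats 1.5–3.5 kcal/g);
  category energy budgets of ~170 kcal/d sweet snacks and ~270 kcal/d
  meat, UK-plausible shares that also guarantee the substitution pools can
  absorb the pathway swaps.
* trade shares Dirichlet over the UK plus 1–3 foreign origins (UK-capable
  foods lean domestic), with UK blue-water factors drawn systematically
  lower than foreign ones — the rainfall mechanism above.
* Gompertz–Makeham all-cause mortality per sex, tuned once to life
  expectancies of ≈79.2 y (male) and ≈82.7 y (female), inside the 78–84
  band of recent UK national statistics; cause-specific rates as smooth
  normal-CDF age ramps of all-cause mortality with old-age plateaus (IHD
  15%, ischemic stroke 5%, type 2 diabetes 1.5%, colorectal cancer 2.7%,
  lung cancer 5.5%, esophageal cancer 1.3%), summing well below 1 at
  every age; a stationary (survival-proportional) age pyramid scaled to
  66.65 million.

Everything is driven by one seed per generator call, restored afterwards,
and written files carry the seed in a comment header; the same seed and
configuration reproduce identical bytes.

What the generator does **not** emulate: per-food energy densities, prices
and footprints are synthetic ranges, not reproductions of the (supplementary-
only) published values. Consequently the *calibrated aggregates and the
scaling arithmetic* reproduce published numbers, while quantities that
depend on the joint per-food distribution — the exact life-expectancy
gain, the footprint deltas, the cost deltas — are only required to land in
plausible bands (gains of months, not days or decades; attribution around
80%; vegetable-first pathways cutting GHGE the most, via larger meat
displacement). A green end-to-end test therefore establishes that the
machinery is correct and the mechanisms have the right signs and ordering,
not that the published table is reproduced digit for digit; that would
require the restricted inputs.

## Numerical choices and degenerate inputs

* Units: g/person/day, kcal, GBP, kg CO₂eq, L internally; per-kg factors
  divided by 1000 at use; national aggregation over a 365-day year.
* Percent changes and national totals are always computed from unrounded
  internals; rounding is display-only (this explains apparent
  inconsistencies when a rounded absolute delta and a rounded percentage
  are read together).
* Zero-baseline foods are retained but frozen in the optimizer; a zero
  denominator never enters the objective.
* Trade shares must sum to 1 within 1e-9 per food; violations are
  reported with the food id. Impacted mortality below zero (impossible
  inputs) is an error, not a clamp-and-continue.
* The life-table horizon defaults to 120 years; the top age group is
  open-ended, implemented by extending the top age's rates.

## Known limitations

Energy is the only nutrient modelled; morbidity (incidence, DALYs) is out
of scope, as are demographic projections with future births, seasonality
of UK production, palatability constraints beyond the deviation objective,
and per-demographic-group diets (national averages only). The health model
is conservative in the same way the underlying method is: only the most
robust diet–disease pairs are included, and poultry, sodium, sugar and
nuts pathways are absent.
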