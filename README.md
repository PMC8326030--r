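# fiveaday

Fruit and vegetable consumption in the United Kingdom sits well below the
national "5-a-day" recommendation (five 80-g portions, 400 g/day, excluding
fruit juice and potatoes, with legumes capped at one portion). `fiveaday`
models national consumption pathways to that target and quantifies what each
pathway would do to population health, diet-related greenhouse-gas emissions
(GHGE), blue water footprint (WF) and diet cost. It is aimed at
public-health and food-policy modellers who want a reproducible, testable
version of this class of diet scenario analysis.

## What it computes

**Pathway optimization.** Starting from a national-average baseline diet
over ~265 food groups, four pathways raise fruit-and-vegetable intake to
400 g/day:

| pathway | increase drawn from | varieties |
|---|---|---|
| `FV_ALL`  | fruit + vegetables + legumes | all |
| `VEG_ALL` | vegetables + legumes | all |
| `FV_UK`   | fruit + vegetables + legumes | UK-capable only |
| `VEG_UK`  | vegetables + legumes | UK-capable only |

Eligible intakes are scaled by a common factor *s* (proportionate to
current consumption) until the counted total reaches 400 g. The energy
added by extra fruit replaces sweet snacks and the energy added by extra
vegetables replaces meat (red, processed, poultry), per kilocalorie.
Total dietary energy is constrained to the baseline level and the total
relative deviation Σ|xᵢ−bᵢ|/bᵢ over all not-directly-modified foods is
minimized by an exact linear-programming solve.

**Health impacts.** A sex-specific annual-cycle life table (IOMLIFET
style) converts the dietary change into life-years gained and change in
life expectancy at birth. Exposure–response relations are log-linear,
RR(Δ) = RR^(Δ/unit), for 13 risk–disease pairs (fruit, vegetables,
legumes, red and processed meat against ischemic heart disease, ischemic
stroke, type 2 diabetes and three cancers); risks on the same outcome
multiply, and effects phase in through normal-CDF time-lag curves (full
effect after 10 y for cardiometabolic disease, after 30 y for cancers with
no effect in the first 10 y).

**Accounting.** Per-capita daily GHGE/WF/cost deltas, and national annual
totals for a population of 66.65 million (Δkg × population × 365 / 10⁹ Mt
CO₂eq/y; ΔL × population × 365 / 10¹² km³/y).

**Synthetic inputs.** The survey, trade, price and mortality data behind
such analyses are restricted, so the package ships a seedable generator
that emulates their structure: 48 fruit / 64 vegetable (incl. legume) /
153 other food groups with heavy-tailed intakes, the major named varieties
pinned at their published amounts, and exact calibration of the baseline
aggregates (88 g fruit, 140 g vegetables, 1744 kcal, £6.78, 6.2 kg CO₂eq,
611.4 L per person per day), plus Gompertz–Makeham mortality with
realistic cause-of-death structure.

## Worked example

```r
library(fiveaday)

inputs   <- generate_inputs(generator_config(seed = 42))
analysis <- run_pathway_analysis(inputs)
analysis
#> Pathway analysis vs baseline (1744 kcal, 6.78 GBP, 6.20 kg CO2eq, 611.4 L per person-day)
#>  pathway fv_g delta_ghge_kg delta_wf_l delta_cost_gbp delta_le_months attribution_fv_pct
#>   FV_ALL  400        -0.266      36.68         0.2622            5.96               85.4
#>  VEG_ALL  400        -0.555       9.84         0.0659            5.81               76.7
#>    FV_UK  400        -0.396      20.78         0.1557            5.98               81.7
#>   VEG_UK  400        -0.569       6.78         0.0592            5.89               77.0
```

Each row is one pathway versus the same baseline: all four reach 400 g of
counted fruit and vegetables; the vegetable-first pathways cut GHGE
roughly twice as much because they displace more meat; life expectancy at
birth rises by about half a year, roughly 80% of it attributable to the
fruit-and-vegetable increases themselves (the rest to eating less red and
processed meat). The optimization detail for one pathway:

```r
analysis$results$FV_ALL$optimization
#> Pathway optimization: optimal
#>   scale factor      1.754386
#>   energy moved      fruit 43.0 kcal, veg 59.0 kcal
#>   objective         0 (total relative deviation)
```

The scale factor 400/228 ≈ 1.754 takes baseline fruit from 88 g to 154 g
and vegetables from 140 g to 246 g; the sweet-snack and meat pools absorb
the added energy, so no other food needs to move (objective 0).

## Acceptance script

`scripts/acceptance.R` regenerates the calibrated baseline from scratch,
runs the pathway optimizer and the exposure–response evaluation, and
writes the headline quantities (pathway fruit and vegetable intakes, the
fruit–heart-disease risk reduction) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
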