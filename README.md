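# lenticfilter

Landscape-scale nitrogen retention by lentic water bodies — lakes,
reservoirs, ponds and wetlands — estimated from a water-body inventory and
a soil-surface nitrogen budget, with restoration-scenario simulation and an
economic valuation of the removal service.

## Who this is for

Landscape biogeochemists and water-quality analysts who want to quantify
how much excess nitrogen a region's standing waters remove, where the
preferential loss of *small* water bodies (surface area below 10^4.5 m²,
≈3.16 ha) erodes that service, and what restoring small versus large
wetlands would buy. The package ships a seeded synthetic-landscape
generator that emulates the statistical structure of national land-use and
nutrient-budget data, so the full pipeline runs and is tested entirely
offline; every stage also accepts your own tables in the same schemas.

## The model

**Nitrogen surplus.** Per administrative unit and year, the soil-surface
budget is

```
NS = FERT + MAN + DEP + BNF + STR − CROP        (kg ha⁻¹)
```

Three-year averages around each epoch are downscaled to grid cells —
agricultural surplus spread equally over cropland cells, atmospheric
deposition over non-cropland cells — then aggregated (mass-conserving) to
third-order river basins as `N_sur` (kg ha⁻¹ yr⁻¹).

**Removal kinetics.** Each water body removes nitrogen by first-order
kinetics driven by its hydraulic residence time τ (days) and annual mean
air temperature:

```
τ     = 1.66 · SA^0.24                 (SA in m²)
ln k  = −1.07 · ln τ + 0.29 · T_c − 0.5,   T_c = (temp − 20) / 10
ρ_wet = (1 − e^(−kτ)) · 100            (% of incoming N removed)
```

Because kτ falls with surface area, small bodies are the most efficient
filters per hectare of water.

**Loading.** A body's nitrogen input is `N_in = γ · N_sur · CA`, with the
delivery factor `γ = (Σ f_i·LR_i)·0.2 + 0.3 ∈ [0.3, 0.5]` weighted by the
basin's land-use composition, and the contributing area `CA = α · SA`
(α ∈ [3, 20]), rescaled per basin so that Σ CA never exceeds the basin
area. Removal is `R_wet = N_in · ρ_wet / 100`, aggregated to
`M_wshd = Σ R_wet / A_shd` per basin. Uncertainty in γ (Normal, 25% CV,
truncated) and α (lognormal, truncated) is propagated by 1000 Monte Carlo
draws reported as medians and interquartile ranges.

**Fractal deficit and scenarios.** Undisturbed landscapes follow a
power-law size-frequency distribution `N_w = c·A^d`. Fitting it to bins
above the 10^4.5 m² breakpoint and extrapolating below quantifies the
small-body deficit, whose area defines three equal-area restoration
scenarios: S1 (refill the fractal distribution with small bodies), S2 (ten
equal larger bodies), S3 (one very large body). Basins are also classified
into water-quality risk quadrants from their surplus level (threshold
17 kg ha⁻¹ yr⁻¹), surplus trend and small-water-body trend.

**Valuation.** Removal converts to the cost of equivalent wastewater
treatment, `E_w = R_awet / (C_in − C_out) · T_cost · 1000`, plus a count of
equivalent treatment plants.

## Worked example

```r
library(lenticfilter)
cfg <- landscape_config(seed = 7)          # desk-scale synthetic landscape
res <- run_pipeline(cfg, out_dir = "out", n_draws = 500)

res$fits$national
#> Size-frequency power law: N_w = 6.359e+06 * A^-0.9481
#>   fitted on 5 bins >= 3.16e+04 m2; R2 = 0.9572, p = 0.0038

res$mc
#> Monte Carlo N removal ensemble (500 draws)
#>   national removal: median 0.932 kt yr-1 (IQR 0.18 kt yr-1)
#>   basins: 15; basin-scale median removal 1.48 kg ha-1 yr-1

res$scenario_result
#> Restoration scenario ensemble (500 draws)
#>   baseline national removal (median): 9.167e+05 kg yr-1
#>   S1: +28.4% [IQR 25.9-31.1] (2.59e+05 kg yr-1; restored 1.55e+03 ha)
#>   S2: +25.6% [IQR 21.6-30.0] (2.32e+05 kg yr-1; restored 1.55e+03 ha)
#>   S3: +24.6% [IQR 11.7-37.7] (2.19e+05 kg yr-1; restored 1.55e+03 ha)
```

Reading the output: the fitted exponent `d ≈ −0.95` describes how body
counts fall with size on this landscape; the ensemble puts its total
removal at 0.93 kilotonnes N yr⁻¹; and restoring the small-body deficit
(S1) raises removal by a median 28%, more than the same area as ten larger
bodies (S2) or one very large body (S3) — the size effect the analysis is
built to expose. `out/` holds every intermediate table (bodies, budgets,
basin surplus, per-body removal, risk classes, valuation) as plain CSV and
JSON. A thin command-line wrapper lives at
`inst/scripts/lenticfilter.R` (`run-all`, `generate`).

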