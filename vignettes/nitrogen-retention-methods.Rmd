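---
title: "Methods: landscape nitrogen retention by lentic water bodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape nitrogen retention by lentic water bodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenticfilter)
```

This vignette documents the models implemented by `lenticfilter`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-landscape generator does and does not emulate, and the
numerical choices made where the method left room.

## The removal model and its assumptions

Standing water bodies remove nitrogen mainly through denitrification in
their anoxic sediments. The package treats each body as a first-order
reactor: a fraction `rho_wet = (1 - exp(-k * tau)) * 100` percent of the
nitrogen entering it is removed, where `tau = 1.66 * SA^0.24` days is the
hydraulic residence time predicted from surface area `SA` (m²) and
`ln k = -1.07 ln(tau) + 0.29 * T_c - 0.5` is the rate constant, with the
temperature factor `T_c = (temp - 20) / 10` centred on 20 °C. Two
consequences shape everything downstream:

* `k * tau = exp(0.29 T_c - 0.5) * tau^(-0.07)` decreases with surface
  area, so efficiency falls as bodies grow — small bodies are the best
  filters per unit of incoming load;
* efficiency rises with temperature, so the same body removes more in
  warmer basins.

The model assumes annual mean air temperature is an adequate proxy for
water temperature, that residence time is set by size alone (no
through-flow management), and that the first-order constant calibrated on
monitored water bodies transfers to unmonitored ones. None of these hold
exactly for any single pond; they are landscape-scale approximations.

Nitrogen *loading* couples the body to its catchment:
`N_in = gamma * N_sur * CA` (kg yr⁻¹), where `N_sur` is the basin's
surplus (kg ha⁻¹ yr⁻¹), `CA = alpha * SA` the contributing area, and
`gamma` the fraction of the surplus mobilised toward surface water.
Negative basin surpluses (net sinks) are propagated through the budget
chain but clamp `N_in` at zero — a mass cannot be negative.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| small-body threshold | m² | `10^4.5` | national small-wetland standard; also the observed breakpoint of size-frequency distributions. A different threshold changes the restored area, not the small-vs-large comparison. |
| `gamma` range | – | `[0.3, 0.5]` | span of monitoring/modelling estimates of catchment N delivery; the land-use weighting `gamma = (sum f_i LR_i) * 0.2 + 0.3` maps any composition into this range. |
| loss ratios `LR_i` | – | paddy 0.35, dryland 0.45, forest/grassland 0.10, constructed 0.25 | representative magnitudes for the four land-use classes; configuration, not measurement — replace with regional values when available. |
| `gamma` CV | – | 0.25 | reported uncertainty of delivery estimates; sampled Normal, truncated. |
| `alpha` range | – | `[3, 20]` | empirical watershed-to-water-body area ratios. |
| `alpha` geometric mean / SD | – | `sqrt(60) ≈ 7.75` / 1.6 | the source data behind the ratio distribution are not printed anywhere usable, so the geometric mean defaults to the log-scale midpoint of the range and the geometric SD places ~95% of draws inside it. |
| risk surplus threshold | kg ha⁻¹ yr⁻¹ | 17 | global average N surplus, used to split "currently high" basins. |
| Monte Carlo draws | – | 1000 | stabilises medians well below the parameter spread (two 1000-draw ensembles with different seeds agree on the national median within 2% in the test suite). |
| WWTP valuation: `C_in`, `C_out`, `T_cost`, fx, per-plant removal | mg L⁻¹, CNY m⁻³, CNY/USD, kg yr⁻¹ | 40, 15, 1.3, 6.23, 2.6e5 | representative 2015 values for Chinese municipal treatment plants; all are explicit arguments because the underlying cost references are not reproduced here. |

## The synthetic landscape

The generator exists so that every stage is testable with no external
data. It emulates, under a single root seed with fixed substreams:

* a **truncated power-law size-frequency distribution**: areas are drawn
  by inverse-CDF from a bounded Pareto with density `∝ A^(d-1)` on the
  configured range, which makes half-decade bin counts follow
  `N_w = c A^d` by construction (the test suite refits `d = -0.8` within
  ±0.05 at 50,000 bodies);
* **preferential small-body loss**: each decade, bodies below the
  threshold are removed by independent Bernoulli trials at the configured
  rate; bodies above are never removed — the simplest mechanism that
  reproduces loss confined to small size classes;
* **loss pathways**: each removed body converts to a destination land
  class drawn from a categorical distribution defaulting to the national
  observed shares (49% cropland, 19% forest, 18% grassland, 7%
  constructed, 4% saline-alkali, 3% other);
* **nested basins** (third-order within first-order) with Dirichlet
  land-use compositions, a log-uniform basin-to-water area ratio, and one
  prefecture-like budget unit per third-order basin (this avoids inventing
  a second administrative geometry);
* **budgets** with the six surplus components per year — including both
  neighbouring years of each epoch so three-year averaging is exercised —
  and a per-unit multiplicative input trend across decades so that surplus
  trends differ in sign between units;
* a **temperature field** hierarchical over basins with per-body jitter.

It does **not** emulate spatial coordinates or adjacency (bodies are
linked to basins by identifiers, the tabular equivalent of a spatial
overlay), rivers or paddy fields (excluded from the inventory), climate
time series, gains of new water bodies, or correlation between body size
and land use within a basin. Passing tests therefore demonstrate the
correctness and internal consistency of the computations — mass
conservation, monotonicity, recovery of known generating parameters — not
the empirical accuracy of any headline number for a real region, which
depends on real inventories and budgets supplied in the same table
schemas. Two presets fix the study conditions: `"small"` (2–3 first-order
basins, ~12,000 bodies) for examples and most tests, `"national"` (10
first-order basins, ~200 third-order basins, ~250,000 bodies) for the
ensemble-stability checks.

## Numerical choices

* **Bins** are half-open `[lo, hi)` in log10 area, width 0.5; the
  convention prevents double counting, and log10 areas are rounded to 9
  decimals first so a body of exactly `10^3` m² lands in the upper bin
  despite floating-point log.
* **Bin representative area** is the geometric midpoint `10^((lo+hi)/2)`,
  the natural centre of a logarithmic bin.
* **The power-law fit** is unweighted least squares on (log10 mid, log10
  count) over bins entirely at or above the threshold; at least three
  non-zero bins are required, zero-count bins are excluded with a warning,
  and `|d| < 0.05` is flagged non-fractal. A continuous Pareto MLE serves
  as an independent cross-check in the tests, not as the estimator — the
  deficit construction is explicitly a binned one.
* **The deficit** is floored at zero per bin (not only in total), matching
  its definition as a shortfall against the fitted law bin by bin.
* **Percent change** against a zero baseline is reported as undefined
  (`NA`, flagged), never ±Inf.
* **Truncated sampling** for `gamma` and `alpha` uses resampling rather
  than clipping, avoiding probability atoms at the range boundaries.
* **Contributing-area rescaling** multiplies all CAs in a basin by a
  common factor when their sum exceeds the basin area, making
  `sum(N_in) = gamma * N_sur * A_shd` exactly at saturation.
* **Risk trends** use strict inequalities; exactly zero change is
  classified not-at-risk.
* Mass-conservation identities are asserted at 1e-6 relative; algebraic
  identities (oracle equivalence, rescaling equality) at 1e-9.

## Design decisions where the method was open

* **Units.** Surface area stays in m² for the residence-time relation;
  contributing areas and basin areas are in hectares for the loading and
  aggregation equations, with the single m²→ha conversion (`1 ha = 10^4
  m²`) at the CA boundary.
* **Deposition routing.** Agricultural surplus is allocated to cropland
  cells and deposition to non-cropland cells; a unit with no non-cropland
  cells folds deposition into cropland with a warning (mass must land
  somewhere), while agricultural surplus with no cropland cells is an
  error.
* **`alpha` is drawn per basin per draw**, all bodies in a basin sharing
  it; per-body draws would make the rescaling ill-defined.
* **Scenario placement.** S1's restored bodies take temperature and basin
  (hence surplus) jointly from one donor sampled among the first-order
  basin's existing small bodies — joint sampling preserves the empirical
  temperature–surplus association. S2's ten bodies and S3's single body
  are each placed uniformly at random among the first-order basin's
  third-order basins, the ensemble re-drawn every Monte Carlo iteration.
  One source sentence attaches the single wetland to "S1"; since S1 is
  defined as many small bodies and S3 as one large body, this is read as
  referring to S3. Both S2 and S3 placements are randomised identically,
  so nothing further hinges on the reading.
* **S1 sizes are deterministic** — per-bin deficit counts rounded to whole
  bodies at representative areas — for reproducibility; the rounded S1
  total then defines the common area of S2 and S3, keeping the equal-area
  contract exact rather than approximate.
* **Paired draws.** Scenario gains are computed against the same draw's
  baseline, not the baseline median, so the reported IQRs reflect the
  gain's uncertainty rather than the shared parameter uncertainty.
* **Restored bodies participate in rescaling**: they are added to their
  basin's contributing-area budget, so restoration in an already saturated
  basin redistributes load rather than conjuring new nitrogen.
* **WWTP equivalents** round up — a fractional treatment plant cannot be
  built.

## Problem sizes

The test suite runs desk-scale landscapes (2,000–50,000 bodies) for unit
and property tests, 20 seeded landscapes of 8,000 bodies for the scenario
ordering check, and one ~250,000-body national-preset landscape with two
1000-draw ensembles for seed stability; the whole suite completes in well
under a minute on one CPU.

## Known limitations

* Removal kinetics ignore within-year hydrology (storm bypass, drawdown)
  and any biogeochemical saturation at high load.
* The delivery factor and contributing-area ratio are the only uncertain
  parameters propagated; budget components and temperatures enter as
  point values.
* Basin membership is purely tabular; no routing between basins, so
  upstream removal does not reduce downstream loading.
* The valuation prices only nitrogen removal, at wastewater-treatment
  cost; flood protection, habitat and carbon are outside scope, so the
  resulting value is a lower bound in intent but depends directly on the
  configured treatment-cost parameters.
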