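---
title: "An individual-based daily model of forest carbon budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based daily model of forest carbon budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapflux)
```

## Scope and structure

`gapflux` simulates the daily carbon budget of forest stands with an
individual-tree (gap-model) structure and aggregates net ecosystem
productivity (NEP) across grid cells and forest types. Eight forest
classes are resolved (`forest_types()`), each with one physiological
parameter set. A grid cell (default 10 km × 10 km) carries one forest
type, a coverage fraction, and a representative stand patch on which
individual trees are simulated explicitly; per-tree fluxes are normalized
by the patch area, so all reported fluxes are on a ground-area basis in
kgC m⁻² d⁻¹ (daily) or kgC m⁻² a⁻¹ (annual).

The daily loop couples four sub-models:

1. **Ecoclimate.** Soil temperature relaxes toward air temperature with a
   first-order time constant; a Thornthwaite-type potential
   evapotranspiration drives a single-bucket water balance clamped at
   field capacity.
2. **Canopy production.** A big-leaf light-response integral gives the
   daily maximum GPP, which is scaled by CO₂, soil-water and temperature
   modifiers and capped by the carbon gain supportable from available
   soil nitrogen (`gpp_daily()`).
3. **Tree carbon budget.** Each tree pays maintenance respiration on its
   leaf, fine-root and sapwood pools (a day/night-weighted modified-Q10
   response normalized at 15 °C) and growth respiration on positive net
   assimilate; the remainder accumulates in a nonstructural photosynthate
   buffer. Litterfall removes carbon from the live pools at constant
   daily turnover rates.
4. **Soil decomposition.** Litter is partitioned into ten pools
   (metabolic/structural above- and below-ground litter, three woody
   classes, active/slow/resistant SOM) which decompose at reference
   rates scaled by shared temperature and moisture modifiers, with
   lignin shielding on the structural pools. The respired share leaves
   as heterotrophic respiration; the remainder cascades between pools;
   the respired flux divided by pool C:N is mineralized into the
   available-nitrogen store that feeds back on GPP.

At each calendar year end the buffer is allocated to structure
(`annual_growth()`): a fixed fraction is shed as flower/fruit litter, the
leaf pool refills to its allometric cap, fine roots to a fixed ratio to
leaf, and the remainder (minus a retained reserve) becomes woody growth,
inverted through the allometry to update DBH and height. The annual
fluxes close as `NEP = NPP − R_s` by construction, and the package
maintains exact carbon bookkeeping: over any simulation span, cumulative
NEP equals the change in total vegetation plus soil carbon to floating
point accuracy (this is asserted in the test suite on a seeded 5-cell,
3-year run at 10⁻⁶ relative tolerance).

## Functional forms and the choices behind them

**Temperature response of photosynthesis.** The modifier is a beta-type
response over the cardinal temperatures,
`F_t = ((T_max − T)/(T_max − T_opt)) · ((T − T_min)/(T_opt − T_min))^((T_opt − T_min)/(T_max − T_opt))`,
clamped to zero outside `[T_min, T_max]`. This parameterization is the
standard beta response whose maximum is exactly 1 at `T_opt` and which
vanishes at both cardinal extremes; among the typographically plausible
exponent placements it is the only one with those properties, which the
test suite asserts. Clamping outside the cardinal range avoids complex
powers where the expression is undefined.

**Soil-water modifier.** The exponent placement adopted is
`F_w = min(1, W_s/W_f + max(Rh − 0.5, 0.1))^(W/2)`: the drought-tolerance
exponent `W` applies to the capped term and the square root to the whole.
This is the reading that keeps `F_w` in (0, 1] and monotone in both soil
water and humidity.

**Moisture modifier of decomposition** is the parabola
`G_w = 1 − (W_s/(0.6·W_f) − 1)²` clamped to [0, 1]: zero in dry soil,
optimal at 60 % of field capacity, reduced again near saturation — the
only parenthesization that is a sensible moisture response.

**Decomposition time stepping.** The reference rates are daily, so the
annual heterotrophic respiration is accumulated from daily steps. The
daily flux is the linear rate `S_u·G_t·G_w·shield_u·C_u`, capped at the
pool size; for the pools and modifier ranges used here the effective
daily rate constant is ≪ 1, so the daily linear stepping tracks the
continuous exponential decay closely (the suite checks a slow pool
against the closed form over ten half-lives at 1 %).

**Respired fractions and transfer topology.** The respired share `P_u`
per pool, the pool-to-pool routing and the per-pool C:N ratios are not
fixed by the flux equations; the defaults in `soil_params()` follow
CENTURY conventions (metabolic litter respires a larger fraction than
structural; litter feeds the active pool, woody material the slow pool;
active and slow SOM exchange with a small leak into the resistant pool).
All of them are configuration, not science claimed from a source, and the
transfer rows are validated so the cascade can never create carbon.

**Day/night temperature split.** Daytime mean
`T_d = T_avg + k_d (T_max − T_avg)` with `k_d = 0.5`, and `T_n` chosen so
the day-length-weighted mean recovers `T_avg` exactly — an
energy-consistent two-parameter split used because the respiration model
needs day and night means that standard forcing does not provide.

**Phenology.** A 10-day smoothed air temperature gates the deciduous
canopy fraction at a 5 °C threshold: the effective LAI for photosynthesis
excludes the deciduous fraction outside the growing season, and on the
leaf-off transition the deciduous leaf fraction is shed to litter in
full. Leaf regrowth happens at the annual allocation; the refilled winter
leaf pool of deciduous types represents preformed reserves and respires,
but does not photosynthesize until leaf-on. This is deliberately the
simplest scheme consistent with a daily model that otherwise omits
phenology.

**Allometry and allocation priorities.** Power laws
`wood = a_w·DBH^b_w`, `height = 1.3 + a_h·DBH^b_h`,
`leaf_cap = a_l·DBH^b_l` with per-type coefficients, and a leaf-first,
then fine-root, then wood priority. These coefficients are package
defaults, exposed in `species_table()` and overridable per type; they are
not calibrated against any specific inventory. A year in which
respiration exceeds assimilation leaves a buffer deficit that is repaid
from structural pools (stem first); a tree that cannot cover it is
flagged carbon-starved. No mortality or recruitment is applied — stand
composition is fixed over a run.

## Parameters that matter

| Parameter | Unit | Default | Role |
|---|---|---|---|
| `a_m` | kgC m⁻² h⁻¹ | 0.0018–0.0028 | maximum leaf photosynthesis, per type |
| `k_ext`, `s_slope` | –, per W m⁻² | 0.5, ~2e-5 | canopy extinction, light-response slope |
| `alpha` | – | 150 | assimilation C:N; caps GPP at `alpha · N_s` |
| `r_g` | – | 0.25 | growth respiration coefficient |
| `rk_leaf/froot/wood` | d⁻¹ | 2.4e-3–3.5e-4 | maintenance respiration at 15 °C |
| `s_u` | d⁻¹ | see `soil_params()` | reference decomposition rates of the ten pools |
| `b_lignin` | – | 5.0 | lignin shielding strength on structural litter |
| `e_w` | – | 0.6 | moisture optimum of decomposition |
| `tau_soil` | d | 15 | soil-temperature damping constant |
| `patch_area`, `n_trees` | m², – | 1000, 60 | representative stand definition |
| `spinup_tol` | – | 1e-4 | relative soil-C change per cycle at convergence |

The per-type NDVI bounds (0.033–0.687) and maximum LAI are tabulated for
the coniferous and deciduous/mixed broad-leaved classes; the evergreen
broad-leaved and tropical classes reuse the NDVI bounds with package
default `lai_v` values (9, 8, 10, 11), chosen once as realistic canopy
maxima for those biomes.

## The synthetic forcing module

`synth_weather()` emulates the statistical structure the simulator
assumes from station forcing: a sinusoidal annual temperature cycle with
AR(1) residuals (ρ = 0.7, σ = 3 °C), wet/dry spells from a two-state
first-order chain whose stationary wet-day frequency matches the
archetype with exponentially distributed amounts, beta-distributed
sunshine fractions that differ between wet and dry days, humidity
responsive to both, and noon PAR from an Angström–Prescott transmittance
(a = 0.25, b = 0.50, PAR fraction 0.48) applied to the top-of-atmosphere
noon irradiance. Five climate archetypes span the cold-temperate to
tropical range of the eight forest types. `synth_soil()` draws total
soil carbon lognormally (CV 0.2) around per-type means and splits it in
fixed pool fractions; `synth_grid()` draws NDVI inside the per-type
scene bounds and builds a stand whose initial leaf area matches the
NDVI-derived LAI.

What the generator does **not** emulate: real spatial covariance between
neighboring cells, interpolation artefacts of station networks, snow
cover and snowmelt radiation effects, extreme events beyond what AR(1)
noise produces, and observed NDVI scene statistics. Passing tests
therefore demonstrate internal consistency (conservation, monotonic
responses, equilibration) and correct implementation of the flux
equations — not predictive skill against observed forcing, which
requires real driving data.

## Numerical choices

- **Spin-up** recycles one designated forcing year until the relative
  change of total soil carbon between consecutive cycles falls below
  `spinup_tol` (default 10⁻⁴), up to `spinup_max_cycles` (default 100,
  then flagged non-converged with a warning, not an error). The tree
  state is reset each cycle so the stand does not grow without bound
  while the soil equilibrates; the resistant SOM pool (rate 3.5e-5 d⁻¹)
  has a multi-century time constant, so the cycle-to-cycle criterion
  deliberately measures drift, not absolute distance from the
  centuries-away asymptote.
- **Degenerate inputs** are handled explicitly: zero day length (PAR
  floor, PET = 0), zero LAI or PAR (GPP exactly 0), saturated or empty
  water bucket (clamped), pool-size-capped decomposition fluxes, a
  zero-overlap evaluation or an all-zero contribution denominator raise
  errors rather than returning NaN.
- **Rounding** of reported percentages is half-away-from-zero at two
  decimals (`round_half_up()`), applied only at the reporting layer.
- **Seeding**: every generator consumes one integer seed; grids split
  per-cell streams deterministically from it (`seed + 7919·i`), so
  fixture sets are bit-reproducible.
- **Problem sizes** used in the shipped tests — stands of 5–10 trees,
  grids of 5–8 cells, runs of 1–3 years, spin-ups of tens of cycles —
  were chosen so that the full suite exercises every code path on
  commodity hardware in under a minute while leaving the conservation
  and oracle tolerances (10⁻⁶ to 10⁻¹²) far above accumulated rounding
  error.

## Known limitations

No succession, mortality, recruitment or competition beyond a shared
canopy; one parameter set per forest type (no mixtures within a patch);
no vertical soil layering, freeze–thaw or snow physics; no sub-daily
radiation geometry beyond the noon value; deciduous leaf regrowth only at
the annual step; NetCDF output is not provided — forcing, grids and
results are exchanged as unit-annotated tidy CSV plus YAML/JSON
summaries.
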