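---
title: "Committed ocean deoxygenation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Committed ocean deoxygenation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`o2commit` is a reduced-complexity, emission-driven model of the coupled
climate–ocean-oxygen system, built to study the *zero-emission commitment*
of ocean deoxygenation: how much oxygen the ocean keeps losing after CO₂
emissions stop, through which mechanisms, and where. This vignette is the
package's account of the science: the model equations and their
assumptions, the parameters that matter, the calibration protocol, the
numerical choices, and the limitations a user should know about.

## Model structure

### Ocean transport

The ocean is twelve well-mixed boxes: four surface boxes (low/mid-latitude,
North Atlantic, North Pacific, Southern Ocean; 100 m thick), three
thermocline boxes (100–1200 m, by basin), two mid-depth boxes
(1200–2000 m) and three deep boxes (below 2000 m, including a
Southern-sourced abyssal box). Total volume is 1.3 × 10¹⁸ m³. Transport is
the sum of

- two *overturning cells*, each a closed loop of directed volume flux with
  strength ψ (Sv): a North Atlantic cell (16 Sv: subtropical surface inflow,
  sinking in the North Atlantic, southward deep flow, interior return) and a
  Southern abyssal cell (13 Sv: Southern Ocean surface to the abyss,
  spreading through the deep Indo-Pacific, upwelling south of the
  subtropics); and
- symmetric background *mixing* exchanges, with tens of Sv connecting the
  surface to the thermocline (the box-model analogue of subduction and
  mode-water ventilation) and a few Sv elsewhere.

Because every cell is a closed loop and mixing is symmetric, the net volume
flux into every box is zero by construction; a spatially uniform tracer is
a fixed point, and all volume-weighted tracer integrals are conserved to
round-off. Tracers are advanced with a donor-cell (upwind) explicit scheme;
the annual step is sub-divided so no box exchanges more than half its
volume per sub-step.

### Warming response of the circulation

The slowdown of deep ventilation under warming — the mechanism that
converts surface warming into deep oxygen loss — is *parameterized*, not
dynamically resolved: the Southern cell is scaled by
`max(1 − α_SO · ΔT_SO, floor)` where `ΔT_SO` is the Southern Ocean surface
temperature anomaly, and the Atlantic cell follows a dip-then-recovery
response (an initial weakening proportional to the instantaneous North
Atlantic anomaly that, as the time-integrated anomaly grows, relaxes into a
modest strengthening above baseline, so the Atlantic re-ventilates late in
the run). The underlying three-dimensional dynamics are out of scope; the
parameterization reproduces the phenomenology — sluggish Southern-sourced
deep ventilation, a recovering Atlantic overturning — and its sensitivity
α_SO is a calibration parameter, constrained by the deep ideal-age and
deep-oxygen targets rather than taken from theory.

An *ideal age* tracer measures the consequence: zero at the surface
(relaxed on a 0.05-yr timescale), ageing one year per year in the interior,
transported like any tracer. At steady circulation the equilibrium ages are
exactly the mean residence times implied by the flux matrix, which the test
suite verifies against an independent dense linear solve.

### Atmosphere and heat

The atmosphere is a single carbon reservoir (2.124 Gt C per µatm) with
logarithmic radiative forcing `F = a·ln(pCO₂/278)`, `a = 5.35` W m⁻², and a
one-layer energy balance `C dSAT/dt = F − λ·SAT − H_ocean`. The land
carbon sink is a constant fraction of emissions — it only needs to deliver
the right airborne fraction. Surface ocean boxes relax (0.5-yr timescale)
toward their pre-industrial temperature plus a per-box multiple of the SAT
anomaly; the associated heat flux is the ocean heat uptake `H_ocean`, so
ocean heat content change equals the time-integrated air–sea heat flux
*exactly*.

Numerical note: at an annual step the explicit SAT/restoring coupling has a
gain above one and oscillates, so the runner advances SAT implicitly with
the restoring heat flux linearized in SAT (an exact linear solve, since the
restoring is linear). The exported `step_atmosphere()` retains the plain
explicit contract for standalone use.

### Carbon chemistry and gas exchange

Surface pCO₂ comes from the carbonate-alkalinity approximation (CO₂*,
HCO₃⁻, CO₃²⁻ only; borate and water absorbed into the calibrated constant
alkalinity), with Lueker et al. (2000) dissociation constants and the Weiss
(1974) solubility. `solve_pco2()` uses safeguarded bracketing on [H⁺] to
10⁻⁶ relative tolerance; the annual stepping loop uses the exact
closed-form quadratic root of the same system (`CA·h² + K₁(CA−DIC)·h +
K₁K₂(CA−2·DIC) = 0`), and a test pins the two routes together to below
10⁻³ µatm while a brute-force grid search verifies the solver to better
than 0.1 µatm on a 100-point lattice. Oxygen saturation is the Garcia &
Gordon (1992) combined fit (≈ 274.6 µmol kg⁻¹ ≈ 282 mmol m⁻³ at 10 °C,
S = 35). Air–sea exchange uses constant per-gas piston velocities (winds
are fixed in this scenario); oxygen exchange is integrated implicitly
(exponential relaxation to saturation) because its equilibration time
(~0.1 yr) is shorter than the step.

The *abiotic oxygen tracer* is initialized and exchanged identically to O₂
but receives no biological source or sink; with biology disabled the two
tracers coincide identically (a test), and in the full run the abiotic
inventory change is the solubility-driven component of deoxygenation.

### Biogeochemistry

Export production out of each surface box is a diagnostic flux —
Michaelis–Menten in phosphate times a Q10 temperature factor — removing
PO₄, NO₃ (16:1) and DIC (112:1) and releasing O₂ (169.6:1). The export is
partitioned over the underlying water column with reference fractions per
depth class (thermocline 0.62, mid 0.14, deep 0.15, bottom 0.09), the
shallow fraction increasing with surface warming (remineralization shoals
as rates rise with temperature). Remineralization in each box is aerobic
(−O₂ : P = 169.6) while O₂ ≥ 5 mmol m⁻³, switches to denitrification
(net −NO₃ : P = 119.68) below that threshold, and halts when nitrate runs
out; whatever cannot be remineralized is forwarded to the box below, and
the bottom residual is redissolved the next year. Phosphorus is therefore
conserved strictly — there are no sediment or weathering fluxes — and
neither O₂ nor NO₃ is ever overdrawn. The 119.68 is interpreted as the
*net* nitrate change per P (consistent with 0.8 × 169.6 − 16); no other
electron acceptors, nitrogen fixation, iron limitation or nutrient runoff
are represented.

## Diagnostics conventions

- Census bins are anchored at zero, left-closed/right-open, width
  10 mmol m⁻³ by default; a value exactly on an edge belongs to the upper
  bin. Threshold volumes use strict `<` (hypoxic < 70, suboxic < 5
  mmol m⁻³), so the suboxic volume nests inside the hypoxic one.
- `commitment_summary()` decomposes an inventory series as realized
  (baseline→stop), committed (stop→evaluation) and total, with the
  total/realized and committed/realized ratios and the realized fraction.
- The heat:oxygen ratio is reported both as the OLS slope of −ΔO₂ against
  Δheat (anomalies from the window start) and as the endpoint ratio, in
  nmol J⁻¹, because either convention is found in the literature.
- pO₂ for the metabolic index is `[O₂]/O₂ˢᵃᵗ(T,S) × 0.21 atm`
  (surface-referenced, no hydrostatic correction): the index uses only pO₂
  *ratios*, which any constant reference leaves unchanged. Temperatures are
  converted to Kelvin internally; Celsius input is the default convention.
  `E₀ = 0.4` eV is the cross-species average hypoxia-vulnerability
  sensitivity; −0.2 eV (oxycline dwellers) flips the sign of the
  temperature term and is exposed for sensitivity runs.
- The `Global Ocean` row of the regional table is computed from all cells
  independently of the regional rows, and both are reported.

## Synthetic gridded fields

`generate_base_field()` produces a seeded latitude × depth × basin tibble
(default 36 bands × 19 levels × 3 basins) with a warm oxygenated surface,
cold deep water, a low-latitude mid-depth oxygen minimum of configurable
amplitude (able to produce suboxic values), cos(latitude)-weighted cell
volumes normalized to 1.3 × 10¹⁸ m³, and Gaussian noise; identical seeds
give bitwise-identical fields. `apply_trend()` adds per-mask linear
anomalies plus noise. These fields exercise every diagnostic — censuses,
masks, budget tables, metabolic-index maps — without any simulator run, and
a property test verifies that prescribed per-mask trends are recovered
within 3 standard errors across 100 seeds. What they do *not* emulate:
circulation-consistent covariance between temperature and oxygen,
seasonality, or observational error structure — so passing recovery tests
demonstrates correctness of the aggregation machinery, not skill against
real ocean atlases.

## Calibration protocol and default choices

The scenario is the idealized commitment experiment: spin-up (10,000 yr)
under 278 µatm, an exponential emission curve `E(y) = E₂₀₂₀·e^{g(y−2020)}`
over 1765–2020 (two parameters; a CSV reader accepts real series), zero
emissions afterwards, integration to 3000, evaluation at 2650 — the
evaluation stops there because multi-century runs of this kind are
eventually interrupted by a qualitatively different Southern Ocean
deep-convection regime that this model does not attempt to represent.

Structural constants (box volumes, water-mass restoring temperatures,
mixing strengths) were fixed first from physical realism: thermocline
ventilation of tens of Sv, deep-water formation temperatures of 0–4 °C,
residence times of ~300 yr (North Atlantic deep water) to ~1400 yr (deep
Indo-Pacific). The remaining free parameters — emission growth rate, land
sink fraction, climate feedback λ, CO₂ piston velocity, Southern slowdown
sensitivity α_SO and Southern surface warming factor, Atlantic
dip/recovery scale, and the phosphorus inventory with the remineralization
depth fractions — were tuned sequentially against the headline state of
the reference experiment: ~411 µatm and ~1 °C in 2020, ~5 Pmol realized
and ~20 Pmol total oxygen loss by 2650, a ~30% solubility share, ~80% of
the committed loss below 2000 m, >10% relative deep-oxygen loss, and a
deep ideal-age rise of several hundred years. The calibrated defaults are
shipped in `default_config()` and `inst/extdata/default_config.yaml`; no
re-tuning is needed to reproduce the package's numbers.

```{r, eval = FALSE}
library(o2commit)
run <- run_commitment()
glance(run)
autoplot(run)
```

## Numerical choices

- Annual coupling step; transport sub-steps capped at Courant 0.5; donor
  upwind differencing (diffusive, monotone — appropriate for box means).
- Spin-up stops when the O₂-inventory drift falls below
  5 × 10⁻⁴ Pmol yr⁻¹ and the global air–sea CO₂ flux below 0.02 Gt C yr⁻¹,
  checked every 500 yr; non-convergence is an error, not a warning.
- The SAT plateau tolerance (0.25 °C over 2020–2650) is a configured
  diagnostic bound, checked on the calibrated run.
- Degenerate inputs are first-class: flat inventory series yield flagged
  NaN ratios; an export demand exceeding available phosphate is capped with
  a warning; overturning scales are floored, never negative; oxygen in
  trend fields is floored at zero with a flag.

## Known limitations

- With one-layer energy balance and constant-fraction land sink, the
  committed ocean CO₂ uptake, the post-stop SAT plateau and the
  observed-scale decadal heat uptake cannot all be matched at once; the
  calibration favors the oxygen-side targets. SAT at 2020 is ~1.14 °C and
  drifts ~0.24 °C over the committed phase — flatter than the forcing
  decline alone would suggest, but not the near-perfect cancellation a
  full Earth-system model produces.
- Committed export change is −9% here (a full model yields a small
  *increase*): with surface temperature flat after the stop, the slowdown
  of the nutrient return flow dominates over Q10-accelerated
  remineralization. Deep respiratory rate changes remain small (the loss is
  residence-time-driven), which is the mechanism that matters.
- Twelve boxes cannot represent within-basin structure: the box-level
  census has no realistic hypoxic-volume distribution (use the synthetic
  fields for census work), and regional table rows are coarse box
  aggregates.
- Salinity is constant; freshwater forcing, sea ice, sediments and
  non-CO₂ forcings are absent by design.
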