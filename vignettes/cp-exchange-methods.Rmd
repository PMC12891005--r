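---
title: "Morphology-based carbon-phosphorus exchange estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphology-based carbon-phosphorus exchange estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Arbuscular mycorrhizal (AM) fungi trade soil phosphorus for plant carbon.
Because the fungus builds its network out of plant carbon and absorbs P
across its hyphal membrane, both sides of the trade can be read off network
*morphology*: the carbon cost of growth scales with hyphal volume
(`V ~ r^2 L`) and the P uptake capacity with hyphal surface (`S ~ r L`).
`myconet` implements this accounting end to end: per-edge cylinder geometry,
convex-hull range and wave speed, a transect-to-radius regressor, carbon and
phosphorus flux estimation with a transporter-limited depletion model, a
radial branching-anastomosis traveling-wave growth model with exchange-rate
feedback, and the resulting isoexchange (Pareto) analysis. A synthetic-data
generator stands in for the robotic-imaging observables so that every stage
is testable against known ground truth.

Package-wide units: edge lengths and radii in um, coordinates in mm, areas
in mm^2, time in hours, masses in ug, concentrations in ug/mL, and the
uptake coefficient J in ng mm^-2 h^-1. All conversions are centralized.

# Flux estimation

**Carbon.** The carbon content of a snapshot is
`Ct = MC * (sum of edge cylinder volumes + sum of spore sphere volumes)`,
with `MC = d_cell * f_dry * f_carbon` the carbon mass per unit cell volume.
`MC` is not measurable for AM fungi directly; the defaults
(1.1 g/cm^3, 0.25, 0.45, giving 124 ug/mm^3) are documented placeholders and
every output carries them, so fitted exchange rates can be rescaled if
better estimates appear. The expenditure rate is `PhiC = (dCt/dt)/CUE`,
where the carbon use efficiency (default 0.5, a typical soil-fungus value)
converts built biomass into consumed carbon. Central differences with an
optional 10 h moving average estimate the derivative; negative derivatives
are floored at zero and flagged (biomass is not un-built at leading order),
and maintenance respiration (proportional to `Ct`) is deliberately excluded.

**Phosphorus.** Uptake is transporter-limited:
`dPf/dt = -J([P]) * S` with Michaelis-Menten `J([P]) = Jmax [P]/([P]+Km)`.
Under saturation, integrating gives `Pf(tm) = Pf(0) - J * integral(S dt)`,
so a regression of measured `Pf` on time-integrated surface area across
harvested replicates calibrates `J` (`calibrate_J()`). Its confidence
interval is a t-interval on the bootstrap standard error over replicates; at
the typical 8 replicates a percentile bootstrap interval is anti-conservative.
`phosphorus_flux()` propagates the calibrated `J` forward with a well-mixed
accessible-pool correction: the accessible concentration is
`(budget - cumulative transfer)/gel volume`, updated with a Heun
(predictor-corrector) step so that 2 h sampling reproduces a fine-step ODE
solution to well under 1%. Cumulative transfer can never exceed the budget.

**Media accounting.** `media_phosphorus()` reconstructs the compartment P
budget from the recipe: KH2PO4 (P mass fraction from standard atomic
masses) plus the P content of the Phytagel gelling agent, minus a 2 ug/mL
adsorbed, inaccessible baseline. The low-P accessible concentration derived
this way is 0.5 ug/mL, and that derived value is used throughout.

**Exchange rate.** `exchange_ratio_fit()` estimates the exchange rate
`kappa = PhiC/PhiP` as the through-origin slope
`sum(PhiC*PhiP)/sum(PhiP^2)` (with a free-intercept variant), with a
replicate-level bootstrap.

# The traveling-wave model

Growing tips (`n`, mm^-2) branch at rate `alpha`, are annihilated by
anastomosis with existing filament at rate `beta*n*rho`, and move radially
with flux `j = c*n - D*grad(n)`; filament density (`rho`, um/mm^2) grows as
`vg*n`. The local gel column is drawn down by Michaelis-Menten uptake over
the local surface density `rhoS = 2*pi*<r>*rho`, with the mean radius set by
the speed-dependent law `<r> = a*v + b`. An integral feedback
`d alpha/dt = -kI*(kappa - kappa0)` holds the instantaneous exchange ratio
at the setpoint.

Numerical scheme (`wave_step()`):

* the time step is locked to `dt = dR/c`, so upwind advection at unit CFL is
  an *exact* one-cell shift of tip mass -- no numerical smearing and exact
  cell-by-cell conservation;
* branching/anastomosis uses a multiplicative exponential update
  (positivity-preserving, exact for frozen coefficients);
* diffusion is explicit centered finite-volume (stability `2*D*dt <= dR^2`
  is enforced at construction);
* carbon and phosphorus fluxes are computed from the realized per-step field
  increments, so the discrete P balance (field deficit versus cumulative
  transfer) is exact by construction;
* uptake in a cell is capped at the P remaining in its column, and branching
  is switched off below a tiny tip density (`n_cutoff`), which regularizes
  the pulled front.

The front is a pulled wave: its realized speed is approximately
`c + 2*sqrt(D*alpha)` and is *always measured from the run*
(`v_wave_fit_um_h`), never assumed. The default advection coefficient
(112 um/h with `D = 1.8e-3 mm^2/h`) was calibrated once so that the
feedback-settled run realizes approximately the 150 um/h reference speed;
faster strategies raise `c`. Denser parameterizations travel with thicker
hyphae via the radius law (defaults `a = 0.024 um/(um/h)`, `b = 0.5 um`,
spanning roughly 1 um at the slowest expansions to 7 um at 300 um/h, the
range over which AM hyphal radii are observed to vary).

**Feedback design.** The only structural requirement on the control law is
that it implement negative integral feedback; its shape is otherwise a
design choice. Three practical choices matter. First, the
feedback kappa is computed from fluxes pooled over a trailing 3 h window, so
derivative noise does not drive the controller. Second, the error
`kappa - kappa0` is clipped (default +/-1): before any region is depleted
the exchange ratio scales like `1/Rwave` and is enormous at early times;
unclipped, this transient winds the branching rate far below its regulated
range and the run never recovers within the 900 h horizon. Third, the gain
(`kI = 6e-4`) was tuned for settling without oscillation against the loop's
dominant delay, which is the depletion lag (the time for newly built density
to dominate the uptake annulus). The controller regulates by moving the
saturated density: with an established depletion front the long-time ratio
is `kappa = rho_C/(CUE*[P]0*d)`, which is monotone in the branching rate.

**Spore carbon.** Spore production is modeled as a carbon flux proportional
to the hyphal length inside a fixed-width maturation annulus behind the
front (default 10 mm), with the coefficient set so spores take roughly a
quarter of carbon expenditure by 100 h. Restricting sporulation to a
maturation zone (rather than the whole colonized disk) is required for a
well-posed model: whole-disk sporulation grows like the disk area while P
supply grows like the front circumference, so the exchange ratio would
diverge and neither the feedback setpoint nor the long-time closed form
would be attainable.

**Growth regimes.** Diagnostics detect `t0` (front speed constant, measured
over a ~20 h stencil to beat grid quantization of the front position) and
`t1` (a depletion front established -- the non-depleted annulus narrower
than the range -- with its width `DeltaR` stabilized). Closed forms for the
established wave, `PhiC = 2*pi*(rho_C/CUE)*v*Rwave + spore term` and
`PhiP = J*2*pi*rho_S*Rwave*DeltaR`, are cross-checked against the simulation
in the sharp-uptake limit (`Km = 0`), where their constant-J, thin-annulus
assumptions hold.

# Pareto front and strategy sweep

Combining the long-time ratio with the radius law and the identity
`rho_C = MC*xi*<r>*rho_S/2` (carbon per unit length over surface per unit
length; `xi = <r^2>/<r>^2`, default 1.2) gives the isoexchange curve

```
rho_S(v) = 2*kappa0*CUE*[P]0*d / (MC*xi*(a*v + b))
```

which is decreasing and convex in `v` and linear in `kappa0`. Equivalent
forms of this relation can be written with a factor `pi` and without the
depth factor, depending on the constant convention; the package derives the
curve from its own long-time ratio so that the convention is internally
consistent, and `isoexchange_curve()` records all constants used as
provenance. The empirical front is a moving maximum of
`rho_S` in order of decreasing speed, exactly as a front over observed
phenotypes is drawn, with no smoothing.

`strategy_sweep()` compares *fixed* phenotypes across environments: each
strategy is a nominal wave speed with its radius-law thickness and a
saturated density taken from the reference-condition isoexchange front, run
with feedback off on a finite plate (default radius 70 mm) for 900 h over a
grid of accessible P concentrations. Feedback must be off here: with the
setpoint active, saturated densities rescale proportionally to `[P]0` and
all environments become equivalent up to a factor, so no optimum can shift.
The default `[P]0` grid spans about two decades around the experimental
accessible concentrations (0.35-90 ug/mL) so both capture regimes appear:
at low `[P]0` every covered region is quickly exhausted and capture is
coverage-limited (fast expansion wins); at high `[P]0` depletion is slow,
capture is uptake-rate-limited, and the denser, thinner-hyphae slow
strategies win once the plate is covered. Total capture per cell is
normalized by its environment-row mean.

# The synthetic-data generator

The generator realizes the study's three input kinds with known ground
truth, under one seeded configuration (`synthetic_run_config()`):

* **Timelapses**: radial "wedge" populations -- each annular shell is filled
  with edges (exponential lengths, mean 250 um) to the target length
  density, each edge carrying a radial position, a front-crossing birth
  time, a class (thin BAS-like or runner) and a lognormal base radius;
  runner radii widen linearly with age (default 0.015 um/h, i.e. 3 to
  4.5 um over 100 h). Ring nodes on the front circle make the convex hull
  track the colonized disk. Full 2-D skeleton geometry is *not* realized:
  every downstream statistic uses only per-edge (r, L), hull area and spore
  radii. Defaults: 150 um/h front speed, 2000 um/mm^2 density (meters of
  hyphae over a 200 h run, the scale of real robotic timelapse morphometry
  with its ~10^6 per-segment radius measurements), spores appearing behind the front at a rate
  that leaves them 10-20% of total biovolume at late times. The spatial law
  of spore placement (uniform over the colonized disk) and the spore radius
  distribution (lognormal around 40 um) are package choices; no published
  law exists.
* **Depletion assays**: per replicate, a fresh population (with lognormal
  replicate-level variation of speed and density, CV 0.1) is integrated to
  its harvest time; `Pf` decreases by `J * integral(S dt)` with additive
  Gaussian noise (default SD 2 ug, a ~2% spectrophotometric error on a
  ~100 ug pool), the root-compartment gel mass stays at baseline, and the
  root receives the transferred P, so total P closes exactly at zero noise.
  Replicates that would go negative are truncated at zero and flagged.
* **Transects**: 120-pixel cylinder-projection profiles -- attenuation
  proportional to the chord depth `2*sqrt(r^2 - x^2)`, integrated over each
  2 um pixel, blurred by a defocus-dependent Gaussian, illumination-scaled,
  with additive noise; augmentation varies defocus over +/-0.1-0.2 mm and
  illumination by +/-20%, and zero-radius background profiles are included.
  Labels span 0-8 um.

What passing tests on this generator do *not* show: real transects carry
structured background (neighboring hyphae, gel texture) rather than white
noise, real networks curve and anastomose rather than being straight chords
in annuli, and real assay errors are not exactly Gaussian. The generator
validates the *estimators* -- their identities, conservation laws, and
round-trip recovery -- not the biology.

# The transect-to-radius regressor

Hyphal radii sit below the low-magnification pixel scale, which is why a
learned regressor is needed at all. The package's default regressor is a
linear model on physically motivated profile features: for an unblurred
cylinder projection the integrated attenuation deficit equals
`absorbance * pi * r^2`, so its square root is linear in the radius; widths
at fractional depths and the deficit's second moment capture blur and
defocus. This feature-based default is closed-form, fully deterministic and
order-invariant; a gradient-boosted alternative (`method = "xgb"`) is
provided. The protocol mirrors the study: a source-grouped 90/10 split (no
source id spans both sets), test-set resampling to the training label
distribution over 20 bins, RMSE and R^2 on the resampled test set, and
per-edge application as the median over per-segment predictions with
sub-0.6 um predictions treated as empty background (below the ~1 um radius
of the thinnest real hyphae). Error statistics achievable on real
micrograph datasets are properties of those datasets and are not targets
here; synthetic round-trip bounds (noiseless RMSE < 0.2 um, monotone
response, and an error floor at the 0.3 um manual annotation noise) stand
in their place.

# Problem sizes and runtimes

The shipped analyses and tests use: 200 h timelapses sampled every 2 h
(~2.3 x 10^4 edges at the final step), 3,000-transect training sets,
8-replicate assays with 100-200 bootstrap/simulation repeats, 900 h model
runs on a 0.1 mm grid (~2,500 cells), and a 4 x 4 strategy sweep at 0.25 mm
resolution. Each piece runs in seconds on one core; the full test suite
completes in a few minutes.

# Known limitations

* The tip flux law is a minimal advection-diffusion form; the realized
  front speed is measured, and mappings from biological rates to speed are
  not claimed.
* The depletion correction treats the compartment as well mixed
  (flux estimation) or as independent vertical columns (wave model); lateral
  diffusion of P in the gel is neglected in both.
* `MC` and `CUE` enter all carbon quantities multiplicatively; fitted
  exchange rates inherit their uncertainty and are interpretable relative to
  the recorded values.
* The generator's replicate variability model (lognormal speed/density
  factors) is a convenience, not an estimate of biological variance.
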