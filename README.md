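# myconet

Morphology-based quantification of reciprocal carbon-phosphorus exchange in
arbuscular mycorrhizal (AM) fungal networks.

AM fungi trade soil phosphorus for plant carbon. Both sides of that trade
can be estimated from network morphology alone: the carbon cost of building
a hyphal segment of length `L` and radius `r` scales with its cylinder
volume (`V = pi r^2 L`), while its capacity to absorb phosphorus scales with
its surface (`S = 2 pi r L`). Given timelapse network graphs, the package
computes the carbon expenditure rate

    PhiC = (dCt/dt) / CUE,      Ct = MC * (sum_i V_i + sum_k V_spore_k)

and, after calibrating the per-area uptake coefficient `J` from phosphorus
depletion assays (`Pf(tm) = Pf(0) - J * integral S dt`), the phosphorus
supply rate

    PhiP = J([P]) * S,          J([P]) = Jmax [P] / ([P] + Km)

with a self-consistent accessible-pool depletion correction. The ratio
`kappa = PhiC/PhiP` is the exchange rate of the symbiosis. A radial
branching-anastomosis traveling-wave model (tips branch, anastomose and
advect; filaments densify; the local gel column is drawn down by
Michaelis-Menten uptake) is extended with negative integral feedback on the
branching rate that holds `kappa` at a setpoint `kappa0`, and yields the
family of isoexchange (Pareto) curves

    rho_S(v) = 2 kappa0 CUE [P]0 d / (MC xi (a v + b))

linking achievable surface density to range-expansion speed at fixed
exchange rate. A seeded synthetic-data generator emulates all study inputs
(timelapse graphs, depletion assays, 120-pixel intensity transects with a
radius regressor) so that every stage is testable against ground truth.

The package is intended for quantitative mycorrhizal biologists and
modelers who want to re-run, probe or extend this style of flux accounting
without access to a robotic imaging line.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_generate_data.R`, then `02` ... `06`), writing
tables under `results/`. Their printed output:

```
timelapse: 101 snapshots to 200 h; final network 5.9 m of hyphae, 111 spores
wave speed: 150.4 um/h (R^2 = 1.0000) over 101 timesteps
train/test: 2727/273 (resampled 273); RMSE = 0.238 um, R^2 = 0.971
media P: 96 ug (3.4 ug/mL) high-P, 70 ug (2.5 ug/mL) low-P; accessible 1.4 / 0.5 ug/mL
calibrated J = 2.66 ng mm^-2 h^-1 (95% CI 1.00-4.33, R^2 = 0.88)
exchange rate kappa = 2.92 (95% CI 2.87-3.00) over 101 timepoints
v150: v = 148.2 um/h, t0 = 27 h, t1 = 155 h, DeltaR(end) = 12.7 mm
   PhiC/PhiP slope (t >= t0) = 2.956; kappa in [2.98, 3.03] after 500 h
best strategy (um/h) per P0 row 0.35/1.4/22.4/89.6 ug/mL: 150/150/150/75
```

Reading these: the generator's front expands at the configured 150 um/h;
the transect regressor recovers radii to 0.24 um on held-out sources; the
medium recipe holds 96 ug P (high-P) and 70 ug (low-P) of which 1.4 and
0.5 ug/mL are accessible; the depletion regression recovers an uptake
coefficient whose confidence interval covers the generating
3 ng mm^-2 h^-1; the measured exchange rate on the synthetic study is
about 3 ug C per ug P; the feedback simulation holds `PhiC = 3 PhiP`
through the traveling-wave phase; and the optimal expansion speed shifts
from fast at scarce P to slow-and-dense at abundant P.

A minimal in-R session:

```r
library(myconet)
cfg   <- synthetic_run_config(seed = 1)
snaps <- generate_timelapse(cfg)
ms    <- morphometry_series(snaps, carbon = carbon_params())
wave_speed(ms$t_h, ms$r_wave_mm)$v_wave_um_h      # ~150

cal <- calibrate_J(generate_depletion_assay(cfg, J_true = 3))
cal$J_ng_mm2_h                                    # ~2.7, CI covers 3

run <- run_simulation(wave_model_params(), T_h = 900)
run$v_wave_fit_um_h                               # ~148
```

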