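#!/usr/bin/env Rscript
# Resource fluxes: carbon expenditure from the carbon-content series,
# transport calibration from the depletion assay, phosphorus supply with the
# accessible-pool correction, the through-origin exchange-rate fit, and the
# media phosphorus accounting.

suppressPackageStartupMessages(library(myconet))
dir.create("results", showWarnings = FALSE)

snaps <- read_snapshots("results/data/snapshots")
ms <- read.csv("results/morphometry.csv")
assay <- read.csv("results/data/assay.csv")
cp <- carbon_params()

# media accounting for both P conditions
hi <- media_phosphorus()
lo <- media_phosphorus(kh2po4_mg_l = 0)
media <- data.frame(condition = c("high-P", "low-P"),
                    total_mass_ug = c(hi$total_mass_ug, lo$total_mass_ug),
                    total_conc_ug_ml = c(hi$total_conc_ug_ml, lo$total_conc_ug_ml),
                    accessible_ug_ml = c(hi$accessible_conc_ug_ml,
                                         lo$accessible_conc_ug_ml))
write.csv(media, "results/media_phosphorus.csv", row.names = FALSE)
cat(sprintf("media P: %.0f ug (%.1f ug/mL) high-P, %.0f ug (%.1f ug/mL) low-P; accessible %.1f / %.1f ug/mL\n",
            hi$total_mass_ug, hi$total_conc_ug_ml, lo$total_mass_ug,
            lo$total_conc_ug_ml, hi$accessible_conc_ug_ml, lo$accessible_conc_ug_ml))

# transport calibration: Pf against time-integrated surface area
cal <- calibrate_J(assay, seed = 1)
cat(sprintf("calibrated J = %.2f ng mm^-2 h^-1 (95%% CI %.2f-%.2f, R^2 = %.2f)\n",
            cal$J_ng_mm2_h, cal$ci[1], cal$ci[2], cal$r_squared))
write.csv(data.frame(J_ng_mm2_h = cal$J_ng_mm2_h, ci_lo = cal$ci[1],
                     ci_hi = cal$ci[2], r_squared = cal$r_squared,
                     Pf0_ug = cal$Pf0_ug),
          "results/calibration.csv", row.names = FALSE)

# fluxes and the exchange rate
ct <- vapply(snaps, total_carbon, numeric(1), params = cp)
pc <- carbon_flux(ms$t_h, ct, CUE = cp$CUE)
tp <- transport_params(J_ng_mm2_h = cal$J_ng_mm2_h,
                       Jmax_ng_mm2_h = cal$J_ng_mm2_h)
pp <- phosphorus_flux(ms$t_h, ms$surface_mm2, tp, hi$accessible_mass_ug)
fit <- exchange_ratio_fit(pc$phi_c_ug_h, pp$phi_p_ug_h, seed = 1)
fluxes <- data.frame(t_h = ms$t_h, Ct_ug = ct, phi_c_ug_h = pc$phi_c_ug_h,
                     surface_mm2 = ms$surface_mm2, phi_p_ug_h = pp$phi_p_ug_h,
                     conc_ug_ml = pp$conc_ug_ml)
write.csv(fluxes, "results/fluxes.csv", row.names = FALSE)
write.csv(binned_average(ms$t_h, pc$phi_c_ug_h, 10),
          "results/phi_c_binned.csv", row.names = FALSE)
cat(sprintf("exchange rate kappa = %.2f (95%% CI %.2f-%.2f) over %d timepoints\n",
            fit$kappa, fit$ci[1], fit$ci[2], fit$n))
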