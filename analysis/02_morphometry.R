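#!/usr/bin/env Rscript
# Network morphometry: totals (L, S, V), convex-hull area, wave radius and
# speed, length/surface/carbon densities, and the volume-weighted radius
# distribution of the final snapshot.

suppressPackageStartupMessages(library(myconet))
dir.create("results", showWarnings = FALSE)

snaps <- read_snapshots("results/data/snapshots")
ms <- morphometry_series(snaps, carbon = carbon_params())
write.csv(ms, "results/morphometry.csv", row.names = FALSE)

ws <- wave_speed(ms$t_h, ms$r_wave_mm)
cat(sprintf("wave speed: %.1f um/h (R^2 = %.4f) over %d timesteps\n",
            ws$v_wave_um_h, ws$r_squared, ws$n))
cat(sprintf("late densities: rho = %.0f um/mm^2, rho_S = %.4f, rho_C = %.4g ug/mm^2\n",
            tail(ms$rho_um_mm2, 1), tail(ms$rho_S, 1), tail(ms$rho_C_ug_mm2, 1)))

final <- snaps[[length(snaps)]]
for (w in c("count", "volume")) {
  d <- radius_distribution(final, w)
  write.csv(d$histogram, sprintf("results/radius_hist_%s.csv", w),
            row.names = FALSE)
}
dv <- radius_distribution(final, "volume")$cdf
med_v <- dv$radius_um[which(dv$cum_mass >= 0.5)[1]]
cat(sprintf("volume-weighted median radius: %.2f um (%d edges)\n",
            med_v, nrow(final$edges)))
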