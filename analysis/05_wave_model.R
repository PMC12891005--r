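#!/usr/bin/env Rscript
# Extended traveling-wave model: the default 900 h run with exchange-rate
# feedback (slow/dense reference strategy) and a faster sparse strategy, plus
# the regime diagnostics (front speed, t0, t1, annulus width, setpoint hold).

suppressPackageStartupMessages(library(myconet))
dir.create("results", showWarnings = FALSE)

report <- function(tag, params) {
  run <- run_simulation(params, T_h = 900, save_every_h = 5)
  f <- run$fluxes
  write.csv(f, sprintf("results/simulation_%s.csv", tag), row.names = FALSE)
  s <- f$t_h >= run$t0_h
  slope <- sum(f$phi_c_ug_h[s] * f$phi_p_ug_h[s]) / sum(f$phi_p_ug_h[s]^2)
  cat(sprintf("%s: v = %.1f um/h, t0 = %.0f h, t1 = %.0f h, DeltaR(end) = %.1f mm\n",
              tag, run$v_wave_fit_um_h, run$t0_h, run$t1_h,
              tail(f$delta_r_mm, 1)))
  cat(sprintf("   PhiC/PhiP slope (t >= t0) = %.3f; kappa in [%.2f, %.2f] after 500 h\n",
              slope, min(f$kappa[f$t_h > 500]), max(f$kappa[f$t_h > 500])))
  invisible(run)
}

report("v150", wave_model_params())
# faster strategy: higher advection, thicker hyphae per the radius law
report("v300", wave_model_params(advection_speed_um_h = 262))
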