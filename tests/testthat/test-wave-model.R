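test_that("parameter construction enforces stability and units", {
  p <- wave_model_params()
  expect_equal(p$dt_h, p$dR_mm / (p$advection_speed_um_h / 1e3))
  expect_equal(p$rbar_um, p$radius_a * p$advection_speed_um_h + p$radius_b)
  expect_error(wave_model_params(D_mm2_h = 1), "stability")
  expect_error(wave_model_params(beta = -1), ">= 0")
})

test_that("a quiescent state (no tips) leaves all fields unchanged", {
  p <- wave_model_params()
  st <- wave_model_init(p, T_h = 50)
  st$n <- rep(0, length(st$n))
  st2 <- wave_step(st, p)
  expect_equal(st2$rho, st$rho)
  expect_equal(st2$P, st$P)
  expect_equal(st2$alpha, st$alpha)
  expect_true(is.na(st2$kappa))
  expect_equal(st2$phi_c_ug_h, 0)
  expect_equal(st2$phi_p_ug_h, 0)
})

test_that("pure advection moves the tip pulse one cell per step, exactly", {
  p <- wave_model_params(alpha0 = 0, beta = 0, D_mm2_h = 0, vg_um_h = 0,
                         alpha_min = 0, feedback = FALSE, kI = 0)
  st <- wave_model_init(p, T_h = 50)
  m0 <- st$n * st$A_mm2
  for (k in 1:10) st <- wave_step(st, p)
  m1 <- st$n * st$A_mm2
  # tip mass is shifted 10 cells outward, conserved cell-by-cell
  expect_equal(m1[(10 + 1):length(m1)], m0[1:(length(m0) - 10)],
               tolerance = 1e-12)
  expect_equal(which.max(m1), which.max(m0) + 10)
})

test_that("discrete P bookkeeping balances the field against the fluxes", {
  p <- wave_model_params()
  st <- wave_model_init(p, T_h = 80)
  removed_via_phi <- 0
  for (k in 1:120) {
    st <- wave_step(st, p)
    removed_via_phi <- removed_via_phi + st$phi_p_ug_h * p$dt_h
  }
  deficit_ug <- sum((p$P0_conc_ug_ml - st$P) * st$A_mm2 * p$gel_depth_mm / 1e3)
  expect_lt(abs(deficit_ug - st$cum_P_ug) / st$cum_P_ug, 1e-6)
  expect_lt(abs(removed_via_phi - st$cum_P_ug) / st$cum_P_ug, 1e-6)
  # positivity of all fields
  expect_true(all(st$rho >= 0) && all(st$n >= 0) && all(st$P >= 0))
  expect_true(all(st$P <= p$P0_conc_ug_ml + 1e-12))
})

test_that("the front travels linearly near the nominal speed", {
  run <- run_simulation(wave_model_params(), T_h = 400, save_every_h = 10)
  expect_gt(run$r_squared, 0.999)
  expect_lt(abs(run$v_wave_fit_um_h - 150) / 150, 0.1)
  expect_true(is.finite(run$t0_h))
  # wave radius non-decreasing
  expect_true(all(diff(run$fluxes$r_wave_mm) >= 0))
})

test_that("halving the grid changes the fitted wave speed by < 3%", {
  v1 <- run_simulation(wave_model_params(feedback = FALSE, kI = 0),
                       T_h = 250, save_every_h = 10)$v_wave_fit_um_h
  v2 <- run_simulation(wave_model_params(feedback = FALSE, kI = 0, dR_mm = 0.05),
                       T_h = 250, save_every_h = 10)$v_wave_fit_um_h
  expect_lt(abs(v1 - v2) / v1, 0.03)
})

test_that("integral feedback holds the exchange ratio at its setpoint", {
  run <- run_simulation(wave_model_params(), T_h = 900, save_every_h = 5)
  f <- run$fluxes
  settled <- f$kappa[f$t_h > 500]
  expect_lt(max(abs(settled - 3) / 3), 0.05)
  # the through-origin slope over the traveling-wave phase matches kappa0
  s <- f$t_h >= run$t0_h
  slope <- sum(f$phi_c_ug_h[s] * f$phi_p_ug_h[s]) / sum(f$phi_p_ug_h[s]^2)
  expect_lt(abs(slope - 3) / 3, 0.05)
})

test_that("without spores the flux ratio decays as 1/Rwave before depletion", {
  p <- wave_model_params(sigma_spore = 0, feedback = FALSE, kI = 0,
                         P0_conc_ug_ml = 1000)
  run <- run_simulation(p, T_h = 400, save_every_h = 10)
  f <- run$fluxes
  s <- f$t_h > 100 & is.finite(f$kappa) & f$kappa > 0
  fit <- lm(log(f$kappa[s]) ~ log(f$r_wave_mm[s]))
  expect_lt(abs(unname(coef(fit)[2]) + 1), 0.1)
  # no depletion at this P0: the non-depleted annulus is the whole range
  expect_equal(f$delta_r_mm[s], f$r_wave_mm[s], tolerance = 0.05)
})

test_that("with depletion established the ratio approaches the closed form", {
  p <- wave_model_params(sigma_spore = 0, feedback = FALSE, kI = 0)
  run <- run_simulation(p, T_h = 900, save_every_h = 10)
  f <- run$fluxes
  st <- run$final
  expect_true(is.finite(run$t1_h))
  # annulus width settles to a constant
  late_dr <- tail(f$delta_r_mm, 5)
  expect_lt((max(late_dr) - min(late_dr)) / max(late_dr), 0.05)
  jf <- findInterval(max(f$r_wave_mm), st$R_mm)
  rho_mid <- mean(st$rho[round(jf * 0.5):round(jf * 0.8)])
  pred <- analytic_regime3_ratio(p$carbon_per_um * rho_mid, p$CUE,
                                 p$P0_conc_ug_ml, p$gel_depth_mm)
  kappa_late <- mean(f$kappa[f$t_h > 700])
  expect_lt(abs(kappa_late - pred) / pred, 0.1)
})

test_that("regime formulas agree with the simulation in the sharp-uptake limit", {
  p <- wave_model_params(sigma_spore = 0, feedback = FALSE, kI = 0, Km_ug_ml = 0)
  run <- run_simulation(p, T_h = 800, save_every_h = 10)
  f <- run$fluxes; st <- run$final
  i <- nrow(f)
  jf <- findInterval(f$r_wave_mm[i], st$R_mm)
  rho_mid <- mean(st$rho[round(jf * 0.6):round(jf * 0.9)])
  rho_C <- p$carbon_per_um * rho_mid
  rho_S <- 2 * pi * p$rbar_um * rho_mid / 1e6
  an <- analytic_regime2_fluxes(rho_C, p$CUE, run$v_wave_fit_um_h,
                                f$r_wave_mm[i], 0, p$Jmax_ng_mm2_h, rho_S,
                                f$delta_r_mm[i])
  expect_lt(abs(f$phi_c_ug_h[i] - an$phi_c_ug_h) / an$phi_c_ug_h, 0.15)
  expect_lt(abs(f$phi_p_ug_h[i] - an$phi_p_ug_h) / an$phi_p_ug_h, 0.15)
})

test_that("analytic regime formulas obey their algebra", {
  # zero wave speed leaves only the spore term
  an <- analytic_regime2_fluxes(1, 0.5, 0, 10, 0.7, 3, 0.02, 10)
  expect_equal(an$phi_c_ug_h, 0.7)
  # PhiC/PhiP falls as 1/Rwave when only Rwave varies (DeltaR fixed)
  r1 <- analytic_regime2_fluxes(1, 0.5, 150, 10, 0, 3, 0.02, 5)
  r2 <- analytic_regime2_fluxes(1, 0.5, 150, 20, 0, 3, 0.02, 5)
  expect_equal((r2$phi_c_ug_h / r2$phi_p_ug_h) /
                 (r1$phi_c_ug_h / r1$phi_p_ug_h), 1, tolerance = 1e-12)
  r3 <- analytic_regime2_fluxes(1, 0.5, 150, 20, 0, 3, 0.02, 20)
  r4 <- analytic_regime2_fluxes(1, 0.5, 150, 10, 0, 3, 0.02, 10)
  expect_equal((r3$phi_c_ug_h / r3$phi_p_ug_h) /
                 (r4$phi_c_ug_h / r4$phi_p_ug_h), 1 / 2, tolerance = 1e-12)

  # long-time ratio: rho_C = 1 ug/mm^2, [P]0 = 1 ug/mm^3 (= 1000 ug/mL), d = 2
  expect_equal(analytic_regime3_ratio(1, 0.5, 1000, 2), 1)
  expect_equal(analytic_regime3_ratio(2, 0.5, 1000, 2), 2)   # linear in rho_C
  expect_error(analytic_regime3_ratio(1, 0.5, 0, 2), "> 0")
})

test_that("depletion width reports the non-depleted annulus", {
  p <- wave_model_params()
  st <- wave_model_init(p, T_h = 100)
  st$n <- rep(0, length(st$n))          # front position defined by rho alone
  # build a front at 10 mm with uniform P: width = wave radius
  st$rho[st$R_mm <= 10] <- 500
  expect_equal(depletion_width(st, p), max(st$R_mm[st$R_mm <= 10]))
  # fully depleted interior disk except a 2 mm annulus
  st$P[st$R_mm <= 8] <- 0
  expect_equal(depletion_width(st, p), max(st$R_mm[st$R_mm <= 10]) - 8,
               tolerance = p$dR_mm * 2)
})

test_that("field blow-up raises an instability error naming the CFL margins", {
  p <- wave_model_params()
  st <- wave_model_init(p, T_h = 50)
  st$rho[5] <- 1e13
  expect_error(wave_step(st, p), "CFL")
})

test_that("lower P0 at fixed setpoint yields lower saturated carbon density", {
  rho_sat <- vapply(c(0.5, 1.4, 4.2), function(P0) {
    run <- run_simulation(wave_model_params(P0_conc_ug_ml = P0),
                          T_h = 700, save_every_h = 20)
    st <- run$final
    jf <- findInterval(max(run$fluxes$r_wave_mm), st$R_mm)
    mean(st$rho[round(jf * 0.6):round(jf * 0.9)])
  }, numeric(1))
  expect_true(all(diff(rho_sat) > 0))
})
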