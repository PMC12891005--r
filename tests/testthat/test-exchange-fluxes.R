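test_that("carbon parameters derive MC in consistent units", {
  cp <- carbon_params()
  expect_equal(cp$MC_ug_mm3, 1.1 * 1000 * 0.25 * 0.45)
  expect_error(carbon_params(f_dry = 1.5), "fractions")
  expect_error(carbon_params(CUE = 0), "CUE")
})

test_that("total carbon sums edge cylinders and spore spheres", {
  cp <- carbon_params(d_cell_g_cm3 = 1, f_dry = 1, f_carbon = 1)  # MC = 1000
  nodes <- data.frame(id = c("a", "b"), x_mm = c(0, 1), y_mm = c(0, 1))
  one <- network_snapshot(0, nodes, data.frame(source = "a", target = "b",
                                               length_um = 1, radius_um = 1))
  # one unit cylinder: pi um^3 = pi*1e-9 mm^3 at MC 1000 -> pi*1e-6 ug
  expect_equal(total_carbon(one, cp), pi * 1e-6)

  empty <- network_snapshot(0, nodes,
                            data.frame(source = character(0), target = character(0),
                                       length_um = numeric(0), radius_um = numeric(0)))
  expect_equal(total_carbon(empty, cp), 0)

  # brute-force per-element oracle on a random fixture
  set.seed(9)
  n <- 30
  edges <- data.frame(source = rep("a", n), target = rep("b", n),
                      length_um = runif(n, 10, 800), radius_um = runif(n, 0.5, 7))
  spores <- data.frame(x_mm = runif(4), y_mm = runif(4), radius_um = runif(4, 20, 60))
  snap <- network_snapshot(1, nodes, edges, spores)
  acc <- 0
  for (i in 1:n) acc <- acc + pi * edges$radius_um[i]^2 * edges$length_um[i]
  for (k in 1:4) acc <- acc + (4 / 3) * pi * spores$radius_um[k]^3
  cp2 <- carbon_params()
  expect_equal(total_carbon(snap, cp2), cp2$MC_ug_mm3 * acc * 1e-9,
               tolerance = 1e-12)
})

test_that("carbon flux differentiates Ct and divides by CUE", {
  t <- seq(0, 100, by = 2)
  # linear Ct with CUE = 0.5 doubles the slope
  f <- carbon_flux(t, 0.3 * t, CUE = 0.5, smoothing_window_h = 0)
  expect_true(all(abs(f$phi_c_ug_h - 0.6) < 1e-12))
  # constant Ct gives zero flux
  f0 <- carbon_flux(t, rep(7, length(t)), CUE = 0.5)
  expect_true(all(f0$phi_c_ug_h == 0))
  # quadratic Ct: central differences are exact for quadratics
  ct <- 0.01 * t^2 + 0.2 * t + 3
  fq <- carbon_flux(t, ct, CUE = 1, smoothing_window_h = 0)
  interior <- 2:(length(t) - 1)
  expect_equal(fq$phi_c_ug_h[interior], 0.02 * t[interior] + 0.2,
               tolerance = 1e-10)
  # shrinking Ct is floored at zero and flagged
  fd <- carbon_flux(c(0, 1, 2), c(3, 2, 1), smoothing_window_h = 0)
  expect_true(all(fd$phi_c_ug_h == 0))
  expect_true(all(fd$floored))
  expect_error(carbon_flux(c(0, 2, 1), c(1, 2, 3)), "increasing")
})

test_that("integrated surface area is a trapezoidal integral", {
  t <- seq(0, 50, by = 2)
  expect_equal(integrated_surface(t, rep(4, length(t)), 50), 200)
  # trapezoid is exact for a linear ramp
  expect_equal(integrated_surface(t, 0.3 * t, 50), 0.3 * 50^2 / 2)
  expect_equal(integrated_surface(t, 0.3 * t, 49), 0.3 * 49^2 / 2)
  # fine-grid Riemann oracle on a curved series
  S <- sqrt(t + 1)
  fine_t <- seq(0, 50, length.out = 20001)
  riemann <- sum(approx(t, S, fine_t)$y) * diff(fine_t)[1]
  expect_equal(integrated_surface(t, S, 50), riemann, tolerance = 1e-3)
  expect_error(integrated_surface(t, S, -2), "outside")
  expect_error(integrated_surface(t, S, 60), "outside")
})

test_that("depletion calibration recovers J exactly without noise", {
  cfg <- clean_config(seed = 7)
  a <- generate_depletion_assay(cfg, J_true = 3)
  cal <- calibrate_J(a, n_boot = 200, seed = 1)
  expect_equal(cal$J_ng_mm2_h, 3, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$Pf0_ug, cfg$P0_mass_ug, tolerance = 1e-9)

  sing <- data.frame(Pf_ug = c(90, 91, 92), intS_mm2h = c(5, 5, 5))
  expect_error(calibrate_J(sing), "singular")

  up <- data.frame(Pf_ug = c(90, 92, 95), intS_mm2h = c(1, 2, 3))
  expect_warning(calibrate_J(up, n_boot = 50), "positive fitted slope")
})

test_that("bootstrap CI covers the true J in most noisy assays", {
  cfg <- quick_config(seed = 1, n_replicates = 8, assay_noise_sd_ug = 1)
  hits <- 0
  n_sim <- 100
  for (i in seq_len(n_sim)) {
    a <- generate_depletion_assay(cfg, J_true = 3, seed = 1000 + i)
    cal <- suppressWarnings(calibrate_J(a, n_boot = 300, seed = i))
    if (cal$ci[1] <= 3 && 3 <= cal$ci[2]) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.9)
})

test_that("phosphorus flux tracks the accessible pool self-consistently", {
  # saturating regime: the worked example network takes up ~1.36 ug/day
  tp <- transport_params(J_ng_mm2_h = 3, Km_ug_ml = 0)
  t <- seq(0, 24, by = 2)
  pf <- phosphorus_flux(t, rep(18.85, length(t)), tp, P_budget_ug = 40)
  expect_equal(pf$phi_p_ug_h[1], 3 * 18.85 / 1000)
  daily <- pf$cum_P_ug[t == 24]
  expect_equal(signif(daily, 1), 1)

  # conservation: cumulative transfer asymptotes to the budget
  tp2 <- transport_params(J_ng_mm2_h = 5, Km_ug_ml = 0, gel_volume_ml = 10)
  t2 <- seq(0, 4000, by = 2)
  pf2 <- phosphorus_flux(t2, rep(50, length(t2)), tp2, P_budget_ug = 2)
  expect_true(all(pf2$cum_P_ug <= 2 + 1e-12))
  expect_gt(max(pf2$cum_P_ug), 1.999)
  expect_true(all(diff(pf2$cum_P_ug) >= 0))
  expect_error(phosphorus_flux(t2, rep(1, length(t2)), tp2, -1), "budget")
})

test_that("explicit pool update matches a fine-step ODE oracle within 1%", {
  # Michaelis-Menten drawdown of a well-mixed pool under a growing surface
  tp <- transport_params(Jmax_ng_mm2_h = 3, Km_ug_ml = 0.3, gel_volume_ml = 28)
  t <- seq(0, 200, by = 2)
  S_fun <- function(tt) 2 + 0.8 * tt        # mm^2, linear growth
  budget <- 20
  pf <- phosphorus_flux(t, S_fun(t), tp, budget)
  ode <- deSolve::ode(
    y = c(P = budget), times = t,
    func = function(tt, y, parms) {
      conc <- max(y[1], 0) / 28
      list(-3e-3 * conc / (conc + 0.3) * S_fun(tt))
    }, method = "lsoda")
  cum_ode <- budget - ode[, "P"]
  i <- which(t >= 50)   # compare once depletion is appreciable
  expect_lt(max(abs(pf$cum_P_ug[i] - cum_ode[i]) / cum_ode[i]), 0.01)
})

test_that("media P accounting reproduces the recipe arithmetic", {
  hi <- media_phosphorus(28, 4.1, 3, 27, 2)
  expect_equal(hi$total_mass_ug, 96, tolerance = 0.01)
  expect_equal(hi$total_conc_ug_ml, 3.4, tolerance = 0.02)
  expect_equal(hi$accessible_conc_ug_ml, 1.4, tolerance = 0.05)
  lo <- media_phosphorus(28, 0, 3, 27, 2)
  expect_equal(lo$total_mass_ug, 70, tolerance = 0.01)
  expect_equal(lo$total_conc_ug_ml, 2.5, tolerance = 0.01)
  expect_equal(lo$accessible_conc_ug_ml, 0.5, tolerance = 0.05)
  zero <- media_phosphorus(28, 0, 0, 27, 2)
  expect_equal(zero$total_mass_ug, 0)
  expect_equal(zero$accessible_conc_ug_ml, 0)
})

test_that("through-origin exchange fit matches its closed form and an oracle", {
  phi_p <- c(1, 2, 3, 4)
  fit <- exchange_ratio_fit(3 * phi_p, phi_p, n_boot = 50)
  expect_equal(fit$kappa, 3)
  expect_equal(unname(fit$ci[2] - fit$ci[1]), 0)

  expect_equal(exchange_ratio_fit(2, 1, n_boot = 10)$kappa, 2)

  # grid-search least-squares oracle on a random fixture
  set.seed(4)
  x <- runif(30, 0.1, 2); y <- 2.7 * x + rnorm(30, 0, 0.3)
  got <- exchange_ratio_fit(y, x, n_boot = 10)$kappa
  grid <- seq(0, 6, by = 1e-4)
  ss <- vapply(grid, function(k) sum((y - k * x)^2), numeric(1))
  expect_equal(got, grid[which.min(ss)], tolerance = 1e-3)

  # scale equivariance: rescaling PhiP by c rescales the slope by 1/c
  expect_equal(exchange_ratio_fit(y, 10 * x, n_boot = 10)$kappa, got / 10,
               tolerance = 1e-12)

  # free-intercept variant
  fi <- exchange_ratio_fit(2 * x + 1, x, through_origin = FALSE, n_boot = 10)
  expect_equal(fi$kappa, 2, tolerance = 1e-9)
  expect_equal(fi$intercept, 1, tolerance = 1e-9)

  expect_error(exchange_ratio_fit(c(1, 2), c(0, 0)), "zero")
})

test_that("binned averages report mean +/- 2 sem per 10-h bin", {
  b <- binned_average(c(1, 2, 3), c(5, 5, 5), 10)
  expect_equal(b$mean, 5)
  expect_equal(b$sem, 0)

  b2 <- binned_average(c(1, 2), c(1, 3), 10)
  expect_equal(b2$mean, 2)
  expect_equal(b2$sem, 1)     # sd = sqrt(2), sem = sqrt(2)/sqrt(2) = 1
  expect_equal(c(b2$ci_lo, b2$ci_hi), c(0, 4))

  # hand computation on a 7-point fixture spanning three bins
  t7 <- c(1, 4, 9, 12, 19, 25, 27)
  v7 <- c(2, 4, 6, 10, 14, 3, 5)
  b7 <- binned_average(t7, v7, 10)
  expect_equal(nrow(b7), 3)
  expect_equal(b7$n, c(3, 2, 2))
  expect_equal(b7$mean, c(4, 12, 4))
  expect_equal(b7$sem[1], sd(c(2, 4, 6)) / sqrt(3))
  expect_equal(b7$sem[2], sd(c(10, 14)) / sqrt(2))
  # empty bins are omitted
  b_gap <- binned_average(c(1, 35), c(1, 2), 10)
  expect_equal(nrow(b_gap), 2)
  expect_error(binned_average(1, 1, 0), "bin_width")
})
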