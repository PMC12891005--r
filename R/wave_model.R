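# Radial branching-anastomosis traveling-wave model with C/P exchange.
#
# Fields on an annular finite-volume grid (cell centers R_j, width dR):
#   rho  hyphal length density, um/mm^2
#   n    growing-tip density, tips/mm^2
#   P    accessible phosphorus concentration in the gel column, ug/mL
# Dynamics:
#   d rho/dt = vg * n
#   d n/dt   = alpha*n - beta*n*rho - div(j),  j = c * n * rhat - D * grad n
#   d alpha/dt = -kI * (kappa - kappa0)        (negative integral feedback)
#   d P/dt   = -J([P]) * rhoS_local / d,       J([P]) = Jmax [P]/([P]+Km)
# with rhoS_local = 2*pi*<r>*rho (dimensionless) and <r> = a*v_nominal + b.
#
# Numerics: the time step is locked to dt = dR / advection_speed, so upwind
# advection at unit CFL is an exact one-cell shift of tip mass (no numerical
# smearing); reactions use a multiplicative exponential update (positivity-
# preserving); diffusion is explicit centered finite-volume. Carbon and
# phosphorus fluxes are computed from the actual per-step field increments,
# so the discrete mass balance is exact by construction.

#' Parameters of the extended traveling-wave model
#'
#' Defaults describe the reference condition: a front propagating at a
#' nominal 150 um/h in a high-P compartment (accessible 1.4 ug/mL) of 3 mm
#' gel depth, with integral feedback holding the C/P exchange rate at
#' `kappa0 = 3` (mass C per mass P). The hyphal radius follows the
#' speed-dependent affine law `<r> = a*v + b`, and `xi = <r^2>/<r>^2`
#' captures the radius-distribution spread. The spore carbon coefficient is
#' set so spore production takes roughly a quarter of carbon expenditure by
#' 100 h.
#'
#' @param vg_um_h tip elongation speed, um/h.
#' @param alpha0 initial branching rate, 1/h.
#' @param beta anastomosis coefficient, mm^2/(um h).
#' @param advection_speed_um_h nominal front advection speed, um/h.
#' @param D_mm2_h tip diffusion, mm^2/h.
#' @param kI integral feedback gain, 1/h per unit kappa.
#' @param kappa0 exchange-rate setpoint, mass C per mass P.
#' @param Jmax_ng_mm2_h,Km_ug_ml Michaelis-Menten P transport.
#' @param P0_conc_ug_ml accessible P concentration ahead of the front.
#' @param gel_depth_mm gel depth d.
#' @param radius_a,radius_b radius law `<r> = a*v + b` (um per um/h, um).
#' @param xi radius-distribution constant `<r^2>/<r>^2` (= 1 + CV^2).
#' @param sigma_spore spore carbon expenditure per um of hyphal length in the
#'   sporulation zone per hour, ug/(um h).
#' @param spore_zone_mm width of the sporulation (maturation) annulus behind
#'   the front in which hyphae spend carbon on spore production; a fixed-width
#'   zone keeps spore expenditure a constant share of total expenditure during
#'   established-wave growth.
#' @param MC_ug_mm3 carbon mass per unit cell volume.
#' @param CUE carbon use efficiency.
#' @param dR_mm radial grid spacing.
#' @param Rmax_mm domain radius; NULL = sized automatically from the horizon.
#' @param alpha_min,alpha_max clamp for the feedback variable.
#' @param n_cutoff tip density below which branching is switched off
#'   (regularizes the pulled front so the realized speed tracks the
#'   advection speed).
#' @param kappa_smooth_h trailing window over which fluxes are pooled before
#'   computing the feedback kappa.
#' @param error_clip bound on the feedback error `kappa - kappa0`; clipping
#'   keeps the very large pre-depletion exchange ratios (kappa ~ 1/Rwave
#'   before any region is depleted) from winding the branching rate far from
#'   its regulated range.
#' @param feedback enable the integral feedback.
#' @return list of class `wave_model_params`.
#' @export
wave_model_params <- function(vg_um_h = 250,
                              alpha0 = 0.19,
                              beta = 4.5e-4,
                              advection_speed_um_h = 112,
                              D_mm2_h = 1.8e-3,
                              kI = 6e-4,
                              kappa0 = 3,
                              Jmax_ng_mm2_h = 3,
                              Km_ug_ml = 0.1,
                              P0_conc_ug_ml = 1.4,
                              gel_depth_mm = 3,
                              radius_a = 0.024,
                              radius_b = 0.5,
                              xi = 1.2,
                              sigma_spore = 4.7e-8,
                              spore_zone_mm = 10,
                              MC_ug_mm3 = 123.75,
                              CUE = 0.5,
                              dR_mm = 0.1,
                              Rmax_mm = NULL,
                              alpha_min = 0.02,
                              alpha_max = 2,
                              n_cutoff = 1e-8,
                              kappa_smooth_h = 3,
                              error_clip = 1,
                              feedback = TRUE) {
  p <- as.list(environment())
  rates <- c(vg_um_h, alpha0, beta, advection_speed_um_h, D_mm2_h, kI, kappa0,
             Jmax_ng_mm2_h, Km_ug_ml, P0_conc_ug_ml, gel_depth_mm, xi,
             sigma_spore, MC_ug_mm3, CUE, dR_mm)
  if (any(!is.finite(rates)) || any(rates < 0)) stop("all rates must be >= 0")
  if (advection_speed_um_h <= 0) stop("advection_speed_um_h must be > 0")
  p$dt_h <- dR_mm / (advection_speed_um_h / 1e3)   # unit-CFL transport
  if (2 * D_mm2_h * p$dt_h > dR_mm^2)
    stop("diffusion violates stability: need 2*D*dt <= dR^2")
  p$rbar_um <- radius_a * advection_speed_um_h + radius_b
  # carbon per um of hyphal length, ug (uses <r^2> = xi * <r>^2)
  p$carbon_per_um <- MC_ug_mm3 * pi * xi * p$rbar_um^2 / UM3_PER_MM3
  structure(p, class = "wave_model_params")
}

#' Initial model state
#'
#' A Gaussian tip pulse at the origin, no hyphae, uniform P at `P0_conc`.
#'
#' @param params a [wave_model_params()].
#' @param T_h horizon used to size the domain when `Rmax_mm` is NULL.
#' @param pulse_amplitude,pulse_sd_mm initial tip pulse shape.
#' @return list of class `wave_state`.
#' @export
wave_model_init <- function(params, T_h = 900, pulse_amplitude = 1,
                            pulse_sd_mm = 0.5) {
  Rmax <- params$Rmax_mm
  if (is.null(Rmax)) {
    # bound on the pulled-front speed: c + 2*sqrt(D*alpha_max)
    v_bound <- params$advection_speed_um_h / 1e3 +
      2 * sqrt(params$D_mm2_h * params$alpha_max)
    Rmax <- v_bound * T_h * 1.02 + 5
  }
  M <- ceiling(Rmax / params$dR_mm)
  edges <- (0:M) * params$dR_mm
  R <- (edges[-1] + edges[-(M + 1)]) / 2
  A <- pi * diff(edges^2)
  structure(list(t_h = 0, R_mm = R, A_mm2 = A, dR_mm = params$dR_mm,
                 rho = rep(0, M),
                 n = pulse_amplitude * exp(-R^2 / (2 * pulse_sd_mm^2)),
                 P = rep(params$P0_conc_ug_ml, M),
                 alpha = params$alpha0,
                 cum_C_ug = 0, cum_P_ug = 0,
                 phi_c_ug_h = 0, phi_p_ug_h = 0, kappa = NA_real_,
                 buf_c = numeric(0), buf_p = numeric(0)),
            class = "wave_state")
}

#' Advance the model state by one time step
#'
#' One explicit update: branching/anastomosis (exponential, positivity
#' preserving), filament densification by tips, Michaelis-Menten P drawdown
#' of the local gel column, unit-CFL upwind advection (exact one-cell shift
#' of tip mass; outflow at Rmax, nothing enters at R = 0), centered diffusion,
#' then the integral feedback on the branching rate using the smoothed
#' exchange ratio (skipped while PhiP = 0).
#'
#' @param state a `wave_state`.
#' @param params a `wave_model_params`.
#' @return updated `wave_state` with per-step `phi_c_ug_h`, `phi_p_ug_h`,
#'   `kappa`.
#' @export
wave_step <- function(state, params) {
  dt <- params$dt_h
  A <- state$A_mm2
  n <- state$n
  # --- branching - anastomosis (growth cutoff below n_cutoff) ---
  growth <- ifelse(n > params$n_cutoff, state$alpha, 0)
  net <- growth - params$beta * state$rho
  n_re <- n * exp(net * dt)
  # --- densification ---
  n_mid <- (n + n_re) / 2
  drho <- params$vg_um_h * n_mid * dt
  rho_new <- state$rho + drho
  built_ug <- params$carbon_per_um * sum(drho * A)
  # spore production in the maturation annulus trailing the front
  Rf <- .front_position(state)
  zone <- state$R_mm <= Rf & state$R_mm > Rf - params$spore_zone_mm
  phi_c <- built_ug / dt / params$CUE +
    params$sigma_spore * sum(state$rho[zone] * A[zone])
  # --- phosphorus drawdown (per-column, exact bookkeeping) ---
  P <- state$P
  Jloc <- ifelse(P > 0, params$Jmax_ng_mm2_h * P / (P + params$Km_ug_ml), 0)
  rhoS_loc <- 2 * pi * params$rbar_um * rho_new / UM2_PER_MM2
  dconc <- pmin(P, Jloc * rhoS_loc / params$gel_depth_mm * dt)
  removed_ug <- sum(dconc * A * params$gel_depth_mm / MM3_PER_ML)
  P_new <- P - dconc
  phi_p <- removed_ug / dt
  # --- transport: exact shift (unit CFL) + explicit diffusion ---
  m <- n_re * A
  m_adv <- c(0, m[-length(m)])
  n_adv <- m_adv / A
  if (params$D_mm2_h > 0) {
    M <- length(n_adv)
    edgesR <- (1:(M - 1)) * state$dR_mm
    flux <- -params$D_mm2_h * diff(n_adv) / state$dR_mm * 2 * pi * edgesR
    dm <- c(-flux, 0) + c(0, flux)
    n_adv <- (n_adv * A + dm * dt) / A
    n_adv[n_adv < 0] <- 0
  }
  if (max(n_adv, rho_new, na.rm = TRUE) > 1e12)
    stop("field blow-up: check CFL margins (dt = dR/advection_speed, 2*D*dt <= dR^2)")
  # --- smoothed exchange ratio and integral feedback ---
  k_steps <- max(1L, round(params$kappa_smooth_h / dt))
  buf_c <- c(state$buf_c, phi_c); buf_p <- c(state$buf_p, phi_p)
  if (length(buf_c) > k_steps) {
    buf_c <- buf_c[(length(buf_c) - k_steps + 1):length(buf_c)]
    buf_p <- buf_p[(length(buf_p) - k_steps + 1):length(buf_p)]
  }
  kappa <- if (sum(buf_p) > 0) sum(buf_c) / sum(buf_p) else NA_real_
  alpha <- state$alpha
  if (params$feedback && params$kI > 0 && is.finite(kappa) && phi_p > 0) {
    err <- min(max(kappa - params$kappa0, -params$error_clip), params$error_clip)
    alpha <- alpha - params$kI * err * dt
    alpha <- min(max(alpha, params$alpha_min), params$alpha_max)
  }
  state$t_h <- state$t_h + dt
  state$rho <- rho_new
  state$n <- n_adv
  state$P <- P_new
  state$alpha <- alpha
  state$cum_C_ug <- state$cum_C_ug + phi_c * dt
  state$cum_P_ug <- state$cum_P_ug + removed_ug
  state$phi_c_ug_h <- phi_c
  state$phi_p_ug_h <- phi_p
  state$kappa <- kappa
  state$buf_c <- buf_c
  state$buf_p <- buf_p
  state
}

# Front position: the traveling tip pulse marks the front; its peak radius is
# robust to slow density drift behind the wave. Falls back to the outermost
# rho-bearing cell when the tip field has died out (e.g. plate edge reached).
.front_position <- function(state) {
  if (max(state$n) > 0 && sum(state$n) > 0) {
    jf <- which.max(state$n)
    return(state$R_mm[jf])
  }
  idx <- which(state$rho > 1e-6 * max(state$rho, 1e-300))
  if (length(idx) == 0) return(0)
  state$R_mm[max(idx)]
}

#' Width of the non-depleted annulus behind the front
#'
#' The radial width of the contiguous annulus, ending at the hyphal front, in
#' which P still exceeds `threshold_fraction * P0`. While no region is yet
#' depleted the width equals the wave radius itself.
#'
#' @param state a `wave_state`.
#' @param params a `wave_model_params` (for P0).
#' @param threshold_fraction depletion threshold (default 0.05).
#' @return width in mm.
#' @export
depletion_width <- function(state, params, threshold_fraction = 0.05) {
  Rw <- .front_position(state)
  if (Rw <= 0) return(0)
  j_front <- findInterval(Rw, state$R_mm)
  thr <- threshold_fraction * params$P0_conc_ug_ml
  behind <- seq_len(j_front)
  dep <- behind[state$P[behind] <= thr]
  if (length(dep) == 0) return(Rw)
  Rw - state$R_mm[max(dep)]
}

#' Run the traveling-wave simulation
#'
#' Integrates the model to the horizon, saving flux diagnostics (and
#' optionally the radial fields) at regular intervals; afterwards fits the
#' realized wave speed from the front trajectory and detects the regime
#' boundaries: `t0_h`, when the front speed becomes constant (within 10% of
#' the late-time fit), and `t1_h`, when a depletion front is established and
#' the non-depleted annulus width stabilizes.
#'
#' @param params a [wave_model_params()].
#' @param T_h simulation horizon, hours.
#' @param save_every_h diagnostics interval.
#' @param save_fields keep radial field snapshots (memory permitting).
#' @param init optional initial `wave_state`.
#' @return list of class `wave_run`: `fluxes` data.frame (`t_h`,
#'   `phi_c_ug_h`, `phi_p_ug_h`, `kappa`, `alpha`, `r_wave_mm`,
#'   `delta_r_mm`, `cum_C_ug`, `cum_P_ug`), `v_wave_fit_um_h`, `r_squared`,
#'   `t0_h`, `t1_h`, `final` state, optionally `fields`.
#' @export
run_simulation <- function(params, T_h = 900, save_every_h = 5,
                           save_fields = FALSE, init = NULL) {
  if (T_h <= 0) stop("T_h must be > 0")
  state <- if (is.null(init)) wave_model_init(params, T_h = T_h) else init
  dt <- params$dt_h
  n_steps <- ceiling(T_h / dt)
  save_stride <- max(1L, round(save_every_h / dt))
  n_saves <- floor(n_steps / save_stride)
  fx <- matrix(NA_real_, nrow = n_saves, ncol = 9,
               dimnames = list(NULL, c("t_h", "phi_c_ug_h", "phi_p_ug_h", "kappa",
                                       "alpha", "r_wave_mm", "delta_r_mm",
                                       "cum_C_ug", "cum_P_ug")))
  fields <- if (save_fields) vector("list", n_saves) else NULL
  s <- 0L
  for (i in seq_len(n_steps)) {
    state <- wave_step(state, params)
    if (i %% save_stride == 0L && s < n_saves) {
      s <- s + 1L
      fx[s, ] <- c(state$t_h, state$phi_c_ug_h, state$phi_p_ug_h, state$kappa,
                   state$alpha, .front_position(state),
                   depletion_width(state, params),
                   state$cum_C_ug, state$cum_P_ug)
      if (save_fields) {
        fields[[s]] <- list(t_h = state$t_h, R_mm = state$R_mm,
                            rho = state$rho, n = state$n, P = state$P)
      }
    }
  }
  fluxes <- as.data.frame(fx[seq_len(s), , drop = FALSE])
  # realized wave speed from the late half of the front trajectory
  late <- fluxes$t_h >= max(fluxes$t_h) / 2 & fluxes$r_wave_mm > 0
  v_fit <- r2 <- NA_real_
  if (sum(late) >= 3) {
    ws <- wave_speed(fluxes$t_h[late], fluxes$r_wave_mm[late])
    v_fit <- ws$v_wave_um_h; r2 <- ws$r_squared
  }
  # t0: first save from which the local front speed (measured over a ~20 h
  # stencil to beat grid quantization of the front position) stays within
  # 10% of the late-time fit
  t0 <- NA_real_
  if (is.finite(v_fit) && v_fit > 0 && nrow(fluxes) >= 6) {
    lag <- max(2L, round(20 / save_every_h))
    m <- nrow(fluxes)
    loc_v <- rep(NA_real_, m)
    i <- (lag + 1):m
    loc_v[i] <- (fluxes$r_wave_mm[i] - fluxes$r_wave_mm[i - lag]) /
      (fluxes$t_h[i] - fluxes$t_h[i - lag]) * 1e3
    ok <- abs(loc_v - v_fit) / v_fit < 0.1
    ok[is.na(ok)] <- FALSE
    run <- rev(cumprod(rev(ok)))   # suffix of all-TRUE
    if (any(run == 1)) t0 <- fluxes$t_h[which(run == 1)[1]]
  }
  # t1: depletion front established (delta_r < r_wave) and width stabilized
  t1 <- NA_real_
  est <- which(fluxes$delta_r_mm < 0.95 * fluxes$r_wave_mm & fluxes$r_wave_mm > 0)
  if (length(est) > 2) {
    dr <- fluxes$delta_r_mm
    for (j in est[-(1:2)]) {
      prev <- dr[(j - 2):j]
      if (all(is.finite(prev)) && max(prev) > 0 &&
          (max(prev) - min(prev)) / max(prev) < 0.05) { t1 <- fluxes$t_h[j]; break }
    }
  }
  structure(list(params = params, fluxes = fluxes, fields = fields,
                 v_wave_fit_um_h = v_fit, r_squared = r2,
                 t0_h = t0, t1_h = t1, final = state),
            class = "wave_run")
}

#' Analytic fluxes of the established-wave regime
#'
#' Closed-form expressions valid once the density front travels at constant
#' speed: `PhiC = 2*pi*(rho_C/CUE)*v_wave*Rwave + spore_term` and
#' `PhiP = J * 2*pi*rho_S*Rwave*DeltaR` (thin-annulus approximation of the
#' uptake integral).
#'
#' @param rho_C_ug_mm2 carbon areal density behind the front.
#' @param CUE carbon use efficiency.
#' @param v_wave_um_h wave speed.
#' @param r_wave_mm wave radius.
#' @param spore_term_ug_h carbon spent on spore production, ug/h.
#' @param J_ng_mm2_h uptake coefficient.
#' @param rho_S surface area density (dimensionless).
#' @param delta_r_mm width of the non-depleted annulus.
#' @return list with `phi_c_ug_h` and `phi_p_ug_h`.
#' @export
analytic_regime2_fluxes <- function(rho_C_ug_mm2, CUE, v_wave_um_h, r_wave_mm,
                                    spore_term_ug_h, J_ng_mm2_h, rho_S,
                                    delta_r_mm) {
  vals <- c(rho_C_ug_mm2, CUE, v_wave_um_h, r_wave_mm, spore_term_ug_h,
            J_ng_mm2_h, rho_S, delta_r_mm)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("inputs must be >= 0")
  list(phi_c_ug_h = 2 * pi * (rho_C_ug_mm2 / CUE) * (v_wave_um_h / 1e3) *
         r_wave_mm + spore_term_ug_h,
       phi_p_ug_h = ng_to_ug(J_ng_mm2_h * 2 * pi * rho_S * r_wave_mm * delta_r_mm))
}

#' Long-time exchange ratio with an established depletion front
#'
#' Once the P-depletion front co-moves with the density front, the exchange
#' ratio settles to `kappa = rho_C / (CUE * [P]0 * d)`: the carbon column
#' built per unit area over the phosphorus column available per unit area.
#'
#' @param rho_C_ug_mm2 carbon areal density.
#' @param CUE carbon use efficiency.
#' @param P0_conc_ug_ml P concentration ahead of the front, ug/mL.
#' @param gel_depth_mm gel depth, mm.
#' @return the exchange ratio kappa (mass C per mass P).
#' @export
analytic_regime3_ratio <- function(rho_C_ug_mm2, CUE, P0_conc_ug_ml, gel_depth_mm) {
  denom <- CUE * ug_per_ml_to_ug_per_mm3(P0_conc_ug_ml) * gel_depth_mm
  if (denom <= 0) stop("CUE, P0 and depth must be > 0")
  rho_C_ug_mm2 / denom
}
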