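# Pareto-front analysis: isoexchange curves in (v_wave, rho_S) space,
# empirical moving-maximum fronts from data points, and the strategy sweep
# over wave speed x environmental P concentration.

#' Isoexchange-rate curve in (v_wave, rho_S) space
#'
#' The locus of traveling-wave phenotypes consistent with a fixed exchange
#' rate `kappa0` once the depletion front is established. It follows from the
#' long-time exchange ratio `kappa0 = rho_C/(CUE*[P]0*d)` combined with the
#' speed-dependent radius law `<r> = a*v + b` and the identity
#' `rho_C = MC*xi*<r>*rho_S/2` (per-length carbon over per-length surface):
#'
#'   `rho_S(v) = 2*kappa0*CUE*[P]0*d / (MC*xi*(a*v + b))`
#'
#' The curve is decreasing in v (thicker hyphae cost more carbon per unit
#' surface), convex, and scales linearly with `kappa0`.
#'
#' @param kappa0 exchange rate, mass C per mass P.
#' @param constants list with `CUE`, `P0_conc_ug_ml`, `gel_depth_mm`,
#'   `MC_ug_mm3`, `xi`, `radius_a`, `radius_b` (e.g. a `wave_model_params`).
#' @param vwave_grid wave speeds, um/h.
#' @return data.frame of class `pareto_curve` with `v_wave_um_h`, `rho_S`;
#'   the constants used are kept as attribute `provenance`.
#' @export
isoexchange_curve <- function(kappa0, constants, vwave_grid) {
  need <- c("CUE", "P0_conc_ug_ml", "gel_depth_mm", "MC_ug_mm3", "xi",
            "radius_a", "radius_b")
  miss <- setdiff(need, names(constants))
  if (length(miss) > 0) stop("missing constants: ", paste(miss, collapse = ", "))
  rbar <- constants$radius_a * vwave_grid + constants$radius_b
  if (any(rbar <= 0)) stop("radius law non-positive over the grid")
  rho_C <- kappa0 * constants$CUE *
    ug_per_ml_to_ug_per_mm3(constants$P0_conc_ug_ml) * constants$gel_depth_mm
  # rho_C [ug/mm^2] = MC * xi * rbar[um] * rho_S / 2 * 1e-3
  rho_S <- 2 * rho_C / (constants$MC_ug_mm3 * constants$xi * rbar) * 1e3
  out <- data.frame(v_wave_um_h = vwave_grid, rho_S = rho_S)
  attr(out, "provenance") <- c(list(kappa0 = kappa0), constants[need])
  class(out) <- c("pareto_curve", "data.frame")
  out
}

#' Empirical Pareto front by moving maximum
#'
#' Sorts observed phenotypes by decreasing wave speed and takes the running
#' maximum of `rho_S`: the resulting step polyline bounds the point cloud
#' from above (no observed point lies strictly above it).
#'
#' @param v_wave_um_h,rho_S observed phenotype coordinates.
#' @return data.frame `v_wave_um_h`, `rho_S`, `rho_S_front` ordered by
#'   decreasing speed.
#' @export
empirical_front <- function(v_wave_um_h, rho_S) {
  if (length(v_wave_um_h) == 0) stop("need at least one point")
  o <- order(v_wave_um_h, decreasing = TRUE)
  data.frame(v_wave_um_h = v_wave_um_h[o], rho_S = rho_S[o],
             rho_S_front = cummax(rho_S[o]))
}

#' Strategy sweep: total P transfer across speed and P availability
#'
#' Simulates network growth for every combination of expansion strategy
#' (nominal wave speed, with its radius-law thickness and a saturated density
#' set by the reference-condition isoexchange front) and environment
#' (accessible P concentration) on a finite plate, and reports the total P
#' absorbed by the horizon, normalized per environment row by the row mean.
#' Phenotypes are held fixed across environments (feedback off), so each row
#' compares fixed strategies in a common environment.
#'
#' @param vwave_grid_um_h strategy wave speeds, um/h.
#' @param P0_grid_ug_ml environmental accessible P concentrations, ug/mL.
#' @param T_h horizon (default 900 h).
#' @param base_params template [wave_model_params()]; per-cell copies adjust
#'   speed, radius, density target, and P0.
#' @param plate_radius_mm plate (domain) radius.
#' @param kappa0_ref,P0_ref_ug_ml reference condition defining the strategy
#'   densities via [isoexchange_curve()].
#' @param dR_mm grid resolution of the sweep runs.
#' @return list of class `strategy_sweep`: `Ptot_ug` and `relative` matrices
#'   (rows = P0 values, cols = speeds), `vwave_grid_um_h`, `P0_grid_ug_ml`,
#'   `failed` logical matrix.
#' @export
strategy_sweep <- function(vwave_grid_um_h, P0_grid_ug_ml, T_h = 900,
                           base_params = wave_model_params(),
                           plate_radius_mm = 70,
                           kappa0_ref = base_params$kappa0,
                           P0_ref_ug_ml = base_params$P0_conc_ug_ml,
                           dR_mm = 0.25) {
  if (length(vwave_grid_um_h) < 1 || length(P0_grid_ug_ml) < 1)
    stop("empty sweep grid")
  nv <- length(vwave_grid_um_h); np <- length(P0_grid_ug_ml)
  Ptot <- matrix(NA_real_, nrow = np, ncol = nv,
                 dimnames = list(paste0("P0_", P0_grid_ug_ml),
                                 paste0("v_", vwave_grid_um_h)))
  failed <- matrix(FALSE, nrow = np, ncol = nv)
  ref_curve <- isoexchange_curve(kappa0_ref, base_params, vwave_grid_um_h)
  for (j in seq_len(nv)) {
    v <- vwave_grid_um_h[j]
    rbar <- base_params$radius_a * v + base_params$radius_b
    rho_target <- ref_curve$rho_S[j] * UM2_PER_MM2 / (2 * pi * rbar)
    p <- base_params
    # realized front speed is advection + the pulled-front correction
    # 2*sqrt(D*alpha); subtract it so the strategy realizes ~v nominal
    v_adv <- max(0.5 * v, v - 2 * sqrt(base_params$D_mm2_h * base_params$alpha0) * 1e3)
    p$advection_speed_um_h <- v_adv
    p$dR_mm <- dR_mm
    p$Rmax_mm <- plate_radius_mm
    p$feedback <- FALSE
    p$beta <- p$alpha0 / rho_target
    p$dt_h <- dR_mm / (v_adv / 1e3)
    # radius law evaluated at the nominal strategy speed
    p$rbar_um <- rbar
    p$carbon_per_um <- p$MC_ug_mm3 * pi * p$xi * rbar^2 / UM3_PER_MM3
    if (2 * p$D_mm2_h * p$dt_h > dR_mm^2)
      stop("sweep grid violates diffusion stability; increase dR_mm")
    for (i in seq_len(np)) {
      p$P0_conc_ug_ml <- P0_grid_ug_ml[i]
      res <- tryCatch(run_simulation(p, T_h = T_h, save_every_h = T_h / 10),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failed[i, j] <- TRUE
      } else {
        Ptot[i, j] <- res$final$cum_P_ug
      }
    }
  }
  rel <- Ptot / rowMeans(Ptot, na.rm = TRUE)
  structure(list(Ptot_ug = Ptot, relative = rel,
                 vwave_grid_um_h = vwave_grid_um_h,
                 P0_grid_ug_ml = P0_grid_ug_ml, failed = failed,
                 T_h = T_h, plate_radius_mm = plate_radius_mm,
                 kappa0_ref = kappa0_ref, P0_ref_ug_ml = P0_ref_ug_ml),
            class = "strategy_sweep")
}
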