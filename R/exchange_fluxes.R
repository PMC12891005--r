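#' Carbon accounting parameters
#'
#' The carbon mass per unit cell volume is `MC = d_cell * f_dry * f_carbon`
#' (converted to ug/mm^3). Its precise value for AM fungi is unknown; the
#' defaults (cell density 1.1 g/cm^3, dry-mass fraction 0.25, carbon fraction
#' of dry mass 0.45) are documented placeholders carried through all outputs,
#' so downstream ratios can be reinterpreted under rescaled MC or CUE.
#'
#' @param d_cell_g_cm3 hyphal cell mass density, g/cm^3.
#' @param f_dry dry-mass fraction of wet mass, in (0, 1].
#' @param f_carbon carbon fraction of dry mass, in (0, 1].
#' @param CUE carbon use efficiency: fraction of consumed carbon fixed into
#'   biomass rather than respired. Default 0.5, a typical soil-fungal value.
#' @return list of class `carbon_params` with derived `MC_ug_mm3`.
#' @export
carbon_params <- function(d_cell_g_cm3 = 1.1, f_dry = 0.25, f_carbon = 0.45,
                          CUE = 0.5) {
  if (f_dry <= 0 || f_dry > 1 || f_carbon <= 0 || f_carbon > 1)
    stop("fractions must be in (0, 1]")
  if (CUE <= 0 || CUE > 1) stop("CUE must be in (0, 1]")
  if (d_cell_g_cm3 <= 0) stop("d_cell_g_cm3 must be > 0")
  structure(list(d_cell_g_cm3 = d_cell_g_cm3, f_dry = f_dry, f_carbon = f_carbon,
                 # 1 g/cm^3 = 1000 ug/mm^3
                 MC_ug_mm3 = d_cell_g_cm3 * 1e3 * f_dry * f_carbon,
                 CUE = CUE),
            class = "carbon_params")
}

#' Phosphorus transport parameters
#'
#' Michaelis-Menten surface transport: `J([P]) = Jmax [P] / ([P] + Km)`.
#'
#' @param J_ng_mm2_h calibrated (saturating) uptake coefficient.
#' @param Jmax_ng_mm2_h maximal uptake coefficient; defaults to `J_ng_mm2_h`.
#' @param Km_ug_ml half-saturation P concentration.
#' @param inaccessible_conc_ug_ml P measured but unavailable to fungus and
#'   root (adsorbed at low pH); default 2.
#' @param gel_volume_ml fungal-compartment volume.
#' @param gel_depth_mm agar depth.
#' @return list of class `transport_params`.
#' @export
transport_params <- function(J_ng_mm2_h = 3, Jmax_ng_mm2_h = J_ng_mm2_h,
                             Km_ug_ml = 0.1, inaccessible_conc_ug_ml = 2,
                             gel_volume_ml = 28, gel_depth_mm = 3) {
  vals <- c(J_ng_mm2_h, Jmax_ng_mm2_h, Km_ug_ml, inaccessible_conc_ug_ml,
            gel_volume_ml, gel_depth_mm)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("transport parameters must be >= 0")
  if (J_ng_mm2_h > Jmax_ng_mm2_h) stop("J must not exceed Jmax")
  structure(list(J_ng_mm2_h = J_ng_mm2_h, Jmax_ng_mm2_h = Jmax_ng_mm2_h,
                 Km_ug_ml = Km_ug_ml,
                 inaccessible_conc_ug_ml = inaccessible_conc_ug_ml,
                 gel_volume_ml = gel_volume_ml, gel_depth_mm = gel_depth_mm),
            class = "transport_params")
}

#' Total carbon content of a network snapshot
#'
#' `Ct = MC * (sum of edge cylinder volumes + sum of spore sphere volumes)`.
#'
#' @param snapshot a `network_snapshot`.
#' @param params a [carbon_params()].
#' @return carbon mass, ug.
#' @export
total_carbon <- function(snapshot, params = carbon_params()) {
  stopifnot(inherits(params, "carbon_params"))
  tot <- snapshot_totals(snapshot)
  params$MC_ug_mm3 * (tot$volume_mm3 + tot$spore_volume_mm3)
}

#' Carbon expenditure rate from a carbon-content series
#'
#' `PhiC = (dCt/dt) / CUE`: the host-supplied carbon consumed per hour, where
#' dividing by the carbon use efficiency accounts for respired carbon.
#' Derivatives are central differences (one-sided at the ends) after optional
#' moving-average smoothing of Ct. Negative derivatives are floored at 0 and
#' flagged (biomass is not un-built at leading order); maintenance respiration
#' is deliberately excluded.
#'
#' @param times_h sampling times, strictly increasing.
#' @param ct_ug carbon-content series, ug.
#' @param CUE carbon use efficiency.
#' @param smoothing_window_h moving-average window (0 = none). Default 10 h,
#'   matching the binning used for flux summaries.
#' @return data.frame `t_h`, `phi_c_ug_h`, `floored`.
#' @export
carbon_flux <- function(times_h, ct_ug, CUE = 0.5, smoothing_window_h = 10) {
  n <- length(times_h)
  if (n < 2) stop("need at least 2 timesteps")
  if (any(diff(times_h) <= 0)) stop("times must be strictly increasing")
  if (length(ct_ug) != n) stop("ct_ug and times_h lengths differ")
  ct <- ct_ug
  if (smoothing_window_h > 0 && n >= 3) {
    dt <- stats::median(diff(times_h))
    k <- max(1L, round(smoothing_window_h / dt))
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1 && k <= n) {
      kern <- rep(1 / k, k)
      sm <- as.numeric(stats::filter(ct, kern, sides = 2))
      ct <- ifelse(is.na(sm), ct, sm)
    }
  }
  d <- numeric(n)
  d[1] <- (ct[2] - ct[1]) / (times_h[2] - times_h[1])
  d[n] <- (ct[n] - ct[n - 1]) / (times_h[n] - times_h[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (ct[i + 1] - ct[i - 1]) / (times_h[i + 1] - times_h[i - 1])
  }
  d[abs(d) < 1e-12 * max(abs(ct), 1)] <- 0   # smoothing round-off guard
  floored <- d < 0
  d[floored] <- 0
  data.frame(t_h = times_h, phi_c_ug_h = d / CUE, floored = floored)
}

#' Time-integrated network surface area
#'
#' Trapezoidal integral of S(t) from the first sample to `t_m` (with linear
#' interpolation at `t_m`), the key covariate of the depletion calibration.
#'
#' @param times_h sampling times.
#' @param surface_mm2 surface-area series, mm^2.
#' @param t_m_h upper limit, hours.
#' @return integral in mm^2 h.
#' @export
integrated_surface <- function(times_h, surface_mm2, t_m_h) {
  if (t_m_h < times_h[1] || t_m_h > times_h[length(times_h)])
    stop("t_m_h outside the sampled range")
  keep <- times_h <= t_m_h
  tt <- times_h[keep]; ss <- surface_mm2[keep]
  if (t_m_h > tt[length(tt)]) {
    s_m <- stats::approx(times_h, surface_mm2, xout = t_m_h)$y
    tt <- c(tt, t_m_h); ss <- c(ss, s_m)
  }
  sum(diff(tt) * (utils::head(ss, -1) + utils::tail(ss, -1)) / 2)
}

#' Calibrate the P uptake coefficient J from a depletion assay
#'
#' Least-squares line of `Pf` (ug) against time-integrated surface area
#' (mm^2 h) across replicates; under transporter saturation the slope is `-J`.
#' The confidence interval is a t-interval built on the bootstrap standard
#' error over replicates (a percentile interval undercovers at typical
#' replicate counts of ~8). Replicates flagged `depleted` (Pf truncated at 0)
#' are excluded from the fit.
#'
#' @param assay data.frame with columns `Pf_ug`, `intS_mm2h`, optionally
#'   `depleted`.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return list with `J_ng_mm2_h`, `ci` (length 2), `r_squared`, `Pf0_ug`,
#'   `n`, `slope_positive` flag.
#' @export
calibrate_J <- function(assay, n_boot = 1000, conf = 0.95, seed = 1) {
  a <- assay
  if (!is.null(a$depleted)) a <- a[!a$depleted, , drop = FALSE]
  if (nrow(a) < 3) stop("need at least 3 non-depleted replicates")
  x <- a$intS_mm2h; y <- a$Pf_ug
  if (stats::sd(x) == 0) stop("singular design: all integrated surface areas equal")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (slope > 0) warning("positive fitted slope: no depletion signal")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(length(x), replace = TRUE)
      if (stats::sd(x[i]) == 0) return(NA_real_)
      xb <- x[i]; yb <- y[i]
      -stats::cov(xb, yb) / stats::var(xb) * NG_PER_UG
    }, numeric(1))
  })
  J_hat <- -slope * NG_PER_UG
  se <- stats::sd(boot, na.rm = TRUE)
  q <- stats::qt(1 - (1 - conf) / 2, df = length(x) - 2)
  list(J_ng_mm2_h = J_hat,
       ci = c(J_hat - q * se, J_hat + q * se),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       Pf0_ug = unname(stats::coef(fit)[1]),
       n = length(x),
       slope_positive = slope > 0)
}

#' Phosphorus supply rate with accessible-pool depletion correction
#'
#' `PhiP(t) = J([P](t)) * S(t)` with Michaelis-Menten `J` and the accessible
#' concentration tracked self-consistently in a well-mixed pool:
#' `[P](t) = (P_budget - cumulative transfer)/gel_volume`, updated explicitly
#' per timestep and floored at 0. In the saturating regime (`[P] >> Km`) this
#' reduces to `PhiP = Jmax * S`; cumulative transfer never exceeds the budget.
#'
#' @param times_h sampling times, strictly increasing.
#' @param surface_mm2 network surface series, mm^2.
#' @param transport a [transport_params()].
#' @param P_budget_ug accessible phosphorus mass initially in the
#'   compartment, ug.
#' @return data.frame `t_h`, `conc_ug_ml`, `J_ng_mm2_h`, `phi_p_ug_h`,
#'   `cum_P_ug`.
#' @export
phosphorus_flux <- function(times_h, surface_mm2, transport = transport_params(),
                            P_budget_ug) {
  stopifnot(inherits(transport, "transport_params"))
  if (P_budget_ug < 0) stop("P budget must be >= 0")
  if (any(diff(times_h) <= 0)) stop("times must be strictly increasing")
  n <- length(times_h)
  P_rem <- P_budget_ug
  conc <- J <- phi <- cum <- numeric(n)
  J_of <- function(p_rem) {
    cc <- max(p_rem, 0) / transport$gel_volume_ml
    if (cc <= 0) return(0)
    if (transport$Km_ug_ml == 0) transport$Jmax_ng_mm2_h
    else transport$Jmax_ng_mm2_h * cc / (cc + transport$Km_ug_ml)
  }
  for (i in seq_len(n)) {
    conc[i] <- P_rem / transport$gel_volume_ml
    J[i] <- J_of(P_rem)
    phi[i] <- ng_to_ug(J[i] * surface_mm2[i])
    if (i < n) {
      dt <- times_h[i + 1] - times_h[i]
      # Heun step: predict the end-of-interval flux, then average
      pred_rem <- P_rem - min(phi[i] * dt, P_rem)
      phi_pred <- ng_to_ug(J_of(pred_rem) * surface_mm2[i + 1])
      transfer <- min(0.5 * (phi[i] + phi_pred) * dt, P_rem)
      P_rem <- P_rem - transfer
      cum[i + 1] <- cum[i] + transfer
    }
  }
  data.frame(t_h = times_h, conc_ug_ml = conc, J_ng_mm2_h = J,
             phi_p_ug_h = phi, cum_P_ug = cum)
}

# Standard atomic masses (g/mol)
.ATOMIC_MASS <- c(K = 39.0983, H = 1.008, P = 30.973762, O = 15.999)

#' Phosphorus accounting of the culture medium
#'
#' Total P in a compartment from its KH2PO4 concentration and the P content
#' of the Phytagel gelling agent, with the P mass fraction of KH2PO4 computed
#' from standard atomic masses. The accessible concentration subtracts the
#' adsorbed, inaccessible baseline (2 ug/mL by default). The low-P
#' accessible concentration derived this way is 0.5 ug/mL, and that derived
#' value is used throughout the package.
#'
#' @param volume_ml compartment medium volume, mL.
#' @param kh2po4_mg_l KH2PO4 concentration, mg/L.
#' @param phytagel_g_l Phytagel concentration, g/L.
#' @param phytagel_P_umol_g P content of Phytagel, umol/g.
#' @param inaccessible_conc_ug_ml adsorbed P concentration, ug/mL.
#' @return list with `total_mass_ug`, `total_conc_ug_ml`,
#'   `accessible_conc_ug_ml`, `accessible_mass_ug`.
#' @examples
#' media_phosphorus()                     # high-P condition: ~96 ug, 3.4 ug/mL
#' media_phosphorus(kh2po4_mg_l = 0)      # low-P condition:  ~70 ug, 2.5 ug/mL
#' @export
media_phosphorus <- function(volume_ml = 28, kh2po4_mg_l = 4.1,
                             phytagel_g_l = 3, phytagel_P_umol_g = 27,
                             inaccessible_conc_ug_ml = 2) {
  vals <- c(volume_ml, kh2po4_mg_l, phytagel_g_l, phytagel_P_umol_g,
            inaccessible_conc_ug_ml)
  if (any(vals < 0)) stop("all inputs must be >= 0")
  m <- .ATOMIC_MASS
  kh2po4_molar_mass <- m["K"] + 2 * m["H"] + m["P"] + 4 * m["O"]
  frac_P <- unname(m["P"] / kh2po4_molar_mass)
  # mg/L == ug/mL; umol/g * g/L * (ug/umol P) / 1000 -> ug/mL
  conc <- kh2po4_mg_l * frac_P +
    phytagel_g_l * phytagel_P_umol_g * unname(m["P"]) / 1e3
  acc <- max(0, conc - inaccessible_conc_ug_ml)
  list(total_mass_ug = volume_ml * conc,
       total_conc_ug_ml = conc,
       accessible_conc_ug_ml = acc,
       accessible_mass_ug = volume_ml * acc)
}

#' Exchange-rate fit of carbon expenditure against phosphorus supply
#'
#' Through-origin least squares `PhiC = kappa * PhiP`, i.e.
#' `kappa = sum(PhiC*PhiP)/sum(PhiP^2)`, with a bootstrap confidence interval
#' over replicates (or over points when no replicate ids are given). A
#' free-intercept variant is also reported.
#'
#' @param phi_c_ug_h carbon expenditure rates.
#' @param phi_p_ug_h phosphorus supply rates (paired).
#' @param replicate optional replicate id per point; bootstrap resamples
#'   whole replicates.
#' @param through_origin fit through the origin (default) or free intercept.
#' @param n_boot,conf,seed bootstrap controls.
#' @return list with `kappa`, `ci`, `intercept` (0 for through-origin), `n`.
#' @export
exchange_ratio_fit <- function(phi_c_ug_h, phi_p_ug_h, replicate = NULL,
                               through_origin = TRUE, n_boot = 1000,
                               conf = 0.95, seed = 1) {
  keep <- is.finite(phi_c_ug_h) & is.finite(phi_p_ug_h)
  x <- phi_p_ug_h[keep]; y <- phi_c_ug_h[keep]
  if (length(x) == 0) stop("no finite paired points")
  if (sum(x^2) == 0) stop("all PhiP are zero: slope undefined")
  rep_id <- if (is.null(replicate)) seq_along(x) else replicate[keep]
  est <- function(xi, yi) {
    if (through_origin) c(sum(yi * xi) / sum(xi^2), 0)
    else {
      f <- stats::lm(yi ~ xi)
      c(unname(stats::coef(f)[2]), unname(stats::coef(f)[1]))
    }
  }
  point <- est(x, y)
  ids <- unique(rep_id)
  boot <- if (length(ids) > 1) {
    with_seed(seed, vapply(seq_len(n_boot), function(b) {
      pick <- sample(ids, replace = TRUE)
      i <- unlist(lapply(pick, function(id) which(rep_id == id)))
      if (sum(x[i]^2) == 0) return(NA_real_)
      est(x[i], y[i])[1]
    }, numeric(1)))
  } else point[1]
  alpha <- (1 - conf) / 2
  list(kappa = point[1],
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)),
       intercept = point[2],
       n = length(x))
}

#' Binned means with 95% confidence band
#'
#' Non-overlapping bins from t = 0; per bin, mean, standard error of the mean
#' and the mean +/- 2 sem band. Empty bins are omitted.
#'
#' @param times_h time of each observation.
#' @param values observed values.
#' @param bin_width_h bin width, hours (default 10).
#' @return data.frame `bin_lo`, `bin_hi`, `t_mid`, `n`, `mean`, `sem`,
#'   `ci_lo`, `ci_hi`.
#' @export
binned_average <- function(times_h, values, bin_width_h = 10) {
  if (bin_width_h <= 0) stop("bin_width_h must be > 0")
  keep <- is.finite(times_h) & is.finite(values)
  t <- times_h[keep]; v <- values[keep]
  bin <- floor(t / bin_width_h)
  out <- lapply(sort(unique(bin)), function(b) {
    vi <- v[bin == b]
    m <- mean(vi)
    sem <- if (length(vi) > 1) stats::sd(vi) / sqrt(length(vi)) else 0
    data.frame(bin_lo = b * bin_width_h, bin_hi = (b + 1) * bin_width_h,
               t_mid = (b + 0.5) * bin_width_h, n = length(vi), mean = m,
               sem = sem, ci_lo = m - 2 * sem, ci_hi = m + 2 * sem)
  })
  do.call(rbind, out)
}
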