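#' Configuration for synthetic data generation
#'
#' Bundles the ground-truth parameters of the synthetic study: a fungal
#' network expanding as a traveling wave of constant speed and density behind
#' the front, a two-component lognormal radius mixture (thin BAS-like hyphae
#' and thicker runner hyphae), runner hyphae that widen linearly with age,
#' spores appearing behind the front, surface-area-proportional phosphorus
#' depletion, and cylinder-projection intensity transects.
#'
#' Defaults mirror the study conditions: imaging every 2 h within the <200 h
#' steady-state window, radii spanning roughly 1-7 um with runner hyphae
#' widening from 3 to 4.5 um over 100 h, and a high-P fungal compartment of
#' 28 mL holding 96.4 ug P.
#'
#' @param seed integer; fixes all generated outputs bit-for-bit.
#' @param n_replicates number of replicate plates for assay generation.
#' @param sampling_interval_h imaging interval, hours.
#' @param duration_h timelapse duration, hours.
#' @param v_wave_um_h front expansion speed, um/h.
#' @param rho_target_um_mm2 hyphal length density behind the front, um/mm^2.
#' @param radius_mixture list with components `bas` and `runner`, each a list
#'   `meanlog`, `sdlog` (lognormal, um) and `weight`.
#' @param widening_rate_um_h linear radial growth rate of runner hyphae.
#' @param spore_rate_mm2_h spore appearance rate per mm^2 colonized area per
#'   h; the default keeps spores at roughly 10-20% of total biovolume at late
#'   times.
#' @param spore_radius_meanlog,spore_radius_sdlog lognormal spore radius (um).
#' @param assay_noise_sd_ug additive Gaussian noise on assay masses, ug.
#' @param transect_noise_sd additive Gaussian noise on transect intensities,
#'   relative to local illumination.
#' @param pixel_size_um transect pixel size; the 2 um default leaves most
#'   radii below the pixel scale, the regime the transect regressor targets.
#' @param psf_sigma_um in-focus optical blur (Gaussian sigma, um).
#' @param defocus_blur_um_per_mm extra blur per mm of defocus.
#' @param absorbance_per_um intensity attenuation per um of chord depth.
#' @param P0_mass_ug phosphorus mass initially in the fungal compartment, ug.
#' @param gel_volume_ml fungal-compartment medium volume, mL.
#' @param Pg0_ug baseline P mass in the root-compartment gel, ug.
#' @param Pr0_ug initial P mass in the host root, ug.
#' @param edge_mean_length_um mean generated edge length, um.
#' @param shell_width_mm radial shell width of the wedge representation, mm.
#' @param r0_mm initial colony radius at t = 0, mm.
#' @param n_sources number of source plates/timesteps labelling transects
#'   (used for grouped train/test splitting).
#' @param replicate_cv lognormal coefficient of variation applied to v_wave
#'   and density across replicates in assay generation.
#' @return an object of class `synthetic_run_config`.
#' @export
synthetic_run_config <- function(seed = 1,
                                 n_replicates = 8,
                                 sampling_interval_h = 2,
                                 duration_h = 200,
                                 v_wave_um_h = 150,
                                 rho_target_um_mm2 = 2000,
                                 radius_mixture = list(
                                   bas = list(meanlog = log(1.5), sdlog = 0.25, weight = 0.6),
                                   runner = list(meanlog = log(3.0), sdlog = 0.20, weight = 0.4)
                                 ),
                                 widening_rate_um_h = 0.015,
                                 spore_rate_mm2_h = 5e-4,
                                 spore_radius_meanlog = log(40),
                                 spore_radius_sdlog = 0.2,
                                 assay_noise_sd_ug = 2,
                                 transect_noise_sd = 0.02,
                                 pixel_size_um = 2,
                                 psf_sigma_um = 1.5,
                                 defocus_blur_um_per_mm = 8,
                                 absorbance_per_um = 0.08,
                                 P0_mass_ug = 96.4,
                                 gel_volume_ml = 28,
                                 Pg0_ug = 20,
                                 Pr0_ug = 5,
                                 edge_mean_length_um = 250,
                                 shell_width_mm = 0.5,
                                 r0_mm = 0.5,
                                 n_sources = 24,
                                 replicate_cv = 0.1) {
  if (!is.finite(duration_h) || duration_h <= 0) stop("duration_h must be > 0")
  if (!is.finite(sampling_interval_h) || sampling_interval_h <= 0)
    stop("sampling_interval_h must be > 0")
  rates <- c(v_wave_um_h, rho_target_um_mm2, widening_rate_um_h, spore_rate_mm2_h,
             assay_noise_sd_ug, transect_noise_sd, P0_mass_ug, gel_volume_ml)
  if (any(rates < 0)) stop("rates, densities and masses must be >= 0")
  w <- c(radius_mixture$bas$weight, radius_mixture$runner$weight)
  if (any(w < 0) || sum(w) <= 0) stop("radius mixture weights must be >= 0 and not all 0")
  cfg <- as.list(environment())
  cfg$radius_mixture$bas$weight <- w[1] / sum(w)
  cfg$radius_mixture$runner$weight <- w[2] / sum(w)
  structure(cfg, class = "synthetic_run_config")
}

# Draw per-edge radii from the two-component lognormal mixture.
# Returns list(radius_um, class) where class is "bas" or "runner".
.draw_radius_mixture <- function(n, mixture) {
  cls <- ifelse(stats::runif(n) < mixture$runner$weight, "runner", "bas")
  r <- numeric(n)
  nb <- sum(cls == "bas"); nr <- sum(cls == "runner")
  if (nb > 0) r[cls == "bas"] <- stats::rlnorm(nb, mixture$bas$meanlog, mixture$bas$sdlog)
  if (nr > 0) r[cls == "runner"] <- stats::rlnorm(nr, mixture$runner$meanlog, mixture$runner$sdlog)
  list(radius_um = r, class = cls)
}

# Build the full edge population of one replicate as radial "wedge" shells:
# each annular shell of width shell_width_mm is filled to the target length
# density; each edge gets a radial position, a birth time (front crossing) and
# a base radius. Runner radii widen linearly with age after birth.
.generate_network_population <- function(config, seed = config$seed) {
  with_seed(seed, {
    v_mm_h <- config$v_wave_um_h / 1e3
    R_end <- config$r0_mm + v_mm_h * config$duration_h
    w <- config$shell_width_mm
    n_shell <- ceiling(R_end / w)
    shells <- lapply(seq_len(n_shell), function(k) {
      r_in <- (k - 1) * w; r_out <- k * w
      area <- pi * (r_out^2 - r_in^2)
      target_len <- config$rho_target_um_mm2 * area
      if (target_len <= 0) return(NULL)
      n_guess <- max(1, ceiling(1.5 * target_len / config$edge_mean_length_um) + 10)
      len <- stats::rexp(n_guess, rate = 1 / config$edge_mean_length_um)
      cum <- cumsum(len)
      n_use <- which(cum >= target_len)[1]
      if (is.na(n_use)) n_use <- n_guess
      len <- len[seq_len(n_use)]
      # radial position uniform in area within the shell
      u <- sqrt(stats::runif(n_use, r_in^2, r_out^2))
      theta <- stats::runif(n_use, 0, 2 * pi)
      mix <- .draw_radius_mixture(n_use, config$radius_mixture)
      data.frame(shell = k, pos_mm = u, theta = theta, length_um = len,
                 radius0_um = mix$radius_um, class = mix$class,
                 stringsAsFactors = FALSE)
    })
    pop <- do.call(rbind, shells)
    pop$birth_h <- pmax(0, (pop$pos_mm - config$r0_mm) / v_mm_h)
    pop <- pop[pop$birth_h <= config$duration_h, , drop = FALSE]
    pop$edge_id <- seq_len(nrow(pop))
    # edge endpoints: centered at (pos, theta), random in-plane orientation
    phi <- stats::runif(nrow(pop), 0, 2 * pi)
    half_mm <- pop$length_um / 2e3
    cx <- pop$pos_mm * cos(pop$theta); cy <- pop$pos_mm * sin(pop$theta)
    pop$x1_mm <- cx - half_mm * cos(phi); pop$y1_mm <- cy - half_mm * sin(phi)
    pop$x2_mm <- cx + half_mm * cos(phi); pop$y2_mm <- cy + half_mm * sin(phi)
    pop
  })
}

# Radius of each edge of the population at time t (runner widening).
.population_radius_at <- function(pop, t_h, config) {
  age <- pmax(0, t_h - pop$birth_h)
  pop$radius0_um + ifelse(pop$class == "runner", config$widening_rate_um_h * age, 0)
}

# Ground-truth totals L (um), S (mm^2), V (mm^3) of a population over times.
.population_totals <- function(pop, times_h, config) {
  o <- order(pop$birth_h)
  tb <- pop$birth_h[o]; len <- pop$length_um[o]
  r0 <- pop$radius0_um[o]; run <- pop$class[o] == "runner"
  wr <- config$widening_rate_um_h
  cl <- cumsum(len)
  c_r0l <- cumsum(r0 * len)
  c_r02l <- cumsum(r0^2 * len)
  c_lr <- cumsum(len * run)
  c_r0l_r <- cumsum(r0 * len * run)
  c_r02l_r <- cumsum(r0^2 * len * run)       # unused but cheap; kept for clarity
  c_tbl_r <- cumsum(tb * len * run)
  c_r0tbl_r <- cumsum(r0 * tb * len * run)
  c_tb2l_r <- cumsum(tb^2 * len * run)
  out <- lapply(times_h, function(t) {
    i <- findInterval(t, tb)
    if (i == 0) return(c(L = 0, S = 0, V = 0))
    L <- cl[i]
    # runner radius at t: r0 + wr*(t - tb); S = 2*pi*sum(r*len), V = pi*sum(r^2*len)
    sum_rl <- c_r0l[i] + wr * (t * c_lr[i] - c_tbl_r[i])
    sum_r2l <- c_r02l[i] +
      2 * wr * (t * c_r0l_r[i] - c_r0tbl_r[i]) +
      wr^2 * (t^2 * c_lr[i] - 2 * t * c_tbl_r[i] + c_tb2l_r[i])
    c(L = L, S = um2_to_mm2(2 * pi * sum_rl), V = um3_to_mm3(pi * sum_r2l))
  })
  m <- do.call(rbind, out)
  data.frame(t_h = times_h, length_um = m[, "L"], surface_mm2 = m[, "S"],
             volume_mm3 = m[, "V"])
}

# Pre-generate the spore record: each spore has a birth time, position and
# radius; the spatial law (uniform over the colonized disk) and radius
# distribution (lognormal) are package choices, as no published law exists.
.generate_spores <- function(config, seed) {
  with_seed(seed, {
    dt <- config$sampling_interval_h
    times <- seq(dt, config$duration_h, by = dt)
    v_mm_h <- config$v_wave_um_h / 1e3
    rows <- lapply(times, function(t) {
      R <- config$r0_mm + v_mm_h * (t - dt / 2)
      lambda <- config$spore_rate_mm2_h * pi * R^2 * dt
      n <- stats::rpois(1, lambda)
      if (n == 0) return(NULL)
      u <- R * sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
      data.frame(birth_h = t, x_mm = u * cos(th), y_mm = u * sin(th),
                 radius_um = stats::rlnorm(n, config$spore_radius_meanlog,
                                           config$spore_radius_sdlog))
    })
    sp <- do.call(rbind, rows)
    if (is.null(sp)) sp <- data.frame(birth_h = numeric(0), x_mm = numeric(0),
                                      y_mm = numeric(0), radius_um = numeric(0))
    sp
  })
}

#' Generate a synthetic network timelapse
#'
#' Realizes a traveling-wave network expansion as a sequence of snapshot
#' graphs: hyphal length density behind the front is held near
#' `rho_target_um_mm2`, the front radius grows at `v_wave_um_h`, runner-hypha
#' radii increase at `widening_rate_um_h` after their front-crossing birth
#' time, and spores accumulate behind the front. Each snapshot carries ring
#' nodes on the front circle so the convex hull tracks the colonized disk.
#'
#' @param config a [synthetic_run_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list of `network_snapshot`; attribute `ground_truth` holds the
#'   generator's own per-timestep totals (`t_h`, `length_um`, `surface_mm2`,
#'   `volume_mm3`, `n_spores`, `spore_volume_mm3`, `front_radius_mm`) for
#'   oracle tests, and attribute `population` the full edge record.
#' @export
generate_timelapse <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_run_config"))
  pop <- .generate_network_population(config, seed = seed)
  spores <- .generate_spores(config, seed = seed + 1L)
  times <- seq(0, config$duration_h, by = config$sampling_interval_h)
  v_mm_h <- config$v_wave_um_h / 1e3
  n_ring <- 60L
  ring_theta <- seq(0, 2 * pi, length.out = n_ring + 1L)[-(n_ring + 1L)]
  snaps <- lapply(times, function(t) {
    R <- config$r0_mm + v_mm_h * t
    sel <- pop$birth_h <= t
    e <- pop[sel, , drop = FALSE]
    radius_t <- .population_radius_at(e, t, config)
    node1 <- data.frame(id = paste0("e", e$edge_id, "a"), x_mm = e$x1_mm, y_mm = e$y1_mm)
    node2 <- data.frame(id = paste0("e", e$edge_id, "b"), x_mm = e$x2_mm, y_mm = e$y2_mm)
    ring <- data.frame(id = paste0("front", seq_len(n_ring)),
                       x_mm = R * cos(ring_theta), y_mm = R * sin(ring_theta))
    nodes <- rbind(node1, node2, ring)
    edges <- data.frame(source = node1$id, target = node2$id,
                        length_um = e$length_um, radius_um = radius_t,
                        class = e$class, birth_h = e$birth_h,
                        edge_id = e$edge_id)
    sp <- spores[spores$birth_h <= t, c("x_mm", "y_mm", "radius_um"), drop = FALSE]
    network_snapshot(t, nodes, edges, sp)
  })
  gt <- .population_totals(pop, times, config)
  gt$n_spores <- vapply(times, function(t) sum(spores$birth_h <= t), integer(1))
  gt$spore_volume_mm3 <- vapply(times, function(t) {
    s <- spores$radius_um[spores$birth_h <= t]
    if (length(s) == 0) 0 else um3_to_mm3(sum(spore_volume(s)))
  }, numeric(1))
  gt$front_radius_mm <- config$r0_mm + v_mm_h * times
  attr(snaps, "ground_truth") <- gt
  attr(snaps, "population") <- pop
  snaps
}

#' Generate a synthetic phosphorus-depletion assay table
#'
#' Emulates the harvest experiment: per replicate, a network timelapse is
#' generated (with replicate-level lognormal variation of speed and density),
#' the time-integrated surface area up to the harvest time is computed, and
#' the fungal-compartment P mass follows
#' `Pf(tm) = Pf(0) - J_true * integral(S dt)` plus measurement noise. The
#' root-compartment gel mass `Pg` stays at its baseline and the root mass `Pr`
#' receives the transferred P, so total P is conserved across harvest times up
#' to noise. Replicates whose Pf would go negative are truncated at 0 and
#' flagged `depleted`.
#'
#' @param config a [synthetic_run_config()].
#' @param J_true ground-truth uptake coefficient, ng mm^-2 h^-1.
#' @param harvest_times_h harvest times (recycled over replicates); default
#'   spreads replicates over `(0.3..1) * duration_h`.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return data.frame with columns `replicate_id`, `t_m_h`, `Pf_ug`, `Pg_ug`,
#'   `Pr_ug`, `intS_mm2h`, `depleted`.
#' @export
generate_depletion_assay <- function(config, J_true = 3, harvest_times_h = NULL,
                                     seed = config$seed) {
  stopifnot(inherits(config, "synthetic_run_config"))
  if (!is.finite(J_true) || J_true < 0) stop("J_true must be >= 0")
  n <- config$n_replicates
  if (is.null(harvest_times_h)) {
    harvest_times_h <- seq(0.3 * config$duration_h, config$duration_h, length.out = n)
  }
  harvest_times_h <- rep_len(harvest_times_h, n)
  if (any(harvest_times_h < 0) || any(harvest_times_h > config$duration_h))
    stop("harvest times must lie within the configured duration")
  noise <- with_seed(seed + 7919L,
                     matrix(stats::rnorm(3 * n, 0, config$assay_noise_sd_ug), ncol = 3))
  repl_fac <- with_seed(seed + 104729L,
                        matrix(stats::rlnorm(2 * n, 0, config$replicate_cv), ncol = 2))
  rows <- lapply(seq_len(n), function(i) {
    cfg_i <- config
    cfg_i$v_wave_um_h <- config$v_wave_um_h * repl_fac[i, 1]
    cfg_i$rho_target_um_mm2 <- config$rho_target_um_mm2 * repl_fac[i, 2]
    pop <- .generate_network_population(cfg_i, seed = seed + 13L * i)
    tm <- harvest_times_h[i]
    tt <- seq(0, tm, length.out = 201)
    S <- .population_totals(pop, tt, cfg_i)$surface_mm2
    intS <- sum(diff(tt) * (utils::head(S, -1) + utils::tail(S, -1)) / 2)
    pf_true <- config$P0_mass_ug - ng_to_ug(J_true) * intS
    depleted <- pf_true < 0
    pf_true <- max(0, pf_true)
    transferred <- config$P0_mass_ug - pf_true
    data.frame(replicate_id = i,
               t_m_h = tm,
               Pf_ug = pf_true + noise[i, 1],
               Pg_ug = config$Pg0_ug + noise[i, 2],
               Pr_ug = config$Pr0_ug + transferred + noise[i, 3],
               intS_mm2h = intS,
               depleted = depleted)
  })
  do.call(rbind, rows)
}

# Cylinder-projection transect model: a hypha of radius r attenuates
# transmitted light in proportion to the chord depth 2*sqrt(r^2 - u^2);
# pixels integrate the profile over their width (5-point rule), the optics
# blur it with a defocus-dependent Gaussian, illumination scales it, and
# additive Gaussian noise is applied.
.render_transect <- function(radius_um, config, defocus_mm = 0, illumination = 1,
                             offset_um = 0, n_px = 120L) {
  px <- config$pixel_size_um
  # pixel 61 is centered on the hyphal axis (before sub-pixel jitter)
  centers <- (seq_len(n_px) - 61) * px
  sub <- c(-0.4, -0.2, 0, 0.2, 0.4) * px
  u <- outer(centers, sub, "+") - offset_um
  chord <- matrix(0, nrow = n_px, ncol = length(sub))
  if (radius_um > 0) {
    inside <- abs(u) < radius_um
    chord[inside] <- 2 * sqrt(radius_um^2 - u[inside]^2)
  }
  absorb <- config$absorbance_per_um * rowMeans(chord)
  intensity <- pmax(0.02, 1 - absorb)
  sigma_px <- (config$psf_sigma_um + config$defocus_blur_um_per_mm * abs(defocus_mm)) / px
  if (sigma_px > 0) {
    half <- max(1L, ceiling(4 * sigma_px))
    k <- stats::dnorm(seq(-half, half), sd = sigma_px)
    k <- k / sum(k)
    padded <- c(rep(intensity[1], half), intensity, rep(intensity[n_px], half))
    intensity <- as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + n_px)]
  }
  illumination * intensity
}

#' Generate a synthetic transect training dataset
#'
#' Produces 120-sample intensity profiles with ground-truth radius labels from
#' the cylinder-projection model, including zero-radius "empty" profiles (to
#' limit overestimation of thin hyphae) and, when `augment = TRUE`,
#' defocus (+/- 0.1-0.2 mm) and illumination (+/- 20%) variation. Labels span
#' 0-8 um.
#'
#' @param config a [synthetic_run_config()].
#' @param n_samples number of transects.
#' @param empty_fraction fraction of zero-radius background transects.
#' @param augment apply defocus/illumination augmentation.
#' @param center_jitter randomize the sub-pixel position of the hypha within
#'   the central pixel (on by default; disable for exact-geometry checks).
#' @param labels_um optional vector of ground-truth radii overriding the
#'   default label sampler (recycled to `n_samples`).
#' @param label_noise_sd_um Gaussian noise added to the recorded label
#'   (emulating manual annotation error; the profile is rendered from the
#'   true radius). Default 0.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return data.frame with columns `sample_id`, `source_id`, `label_um`,
#'   `defocus_mm`, `illumination`, and profile columns `p001..p120`.
#' @export
generate_transect_dataset <- function(config, n_samples, empty_fraction = 0.1,
                                      augment = TRUE, center_jitter = TRUE,
                                      labels_um = NULL, label_noise_sd_um = 0,
                                      seed = config$seed) {
  stopifnot(inherits(config, "synthetic_run_config"))
  if (n_samples <= 0) stop("n_samples must be > 0")
  half_width_um <- 120 * config$pixel_size_um / 2
  with_seed(seed, {
    if (is.null(labels_um)) {
      kind <- stats::runif(n_samples)
      r <- numeric(n_samples)
      mix <- .draw_radius_mixture(n_samples, config$radius_mixture)
      r <- pmin(pmax(mix$radius_um, 0.5), 8)
      unif <- kind >= (1 - 0.15)              # heavy-tail coverage up to 8 um
      r[unif] <- stats::runif(sum(unif), 0.5, 8)
      r[kind < empty_fraction] <- 0
    } else {
      r <- rep_len(labels_um, n_samples)
    }
    if (any(r >= half_width_um))
      stop("radius exceeds half the physical transect width")
    defocus <- if (augment) {
      sample(c(-1, 1), n_samples, TRUE) * stats::runif(n_samples, 0, 0.2) *
        (stats::runif(n_samples) < 0.5)
    } else rep(0, n_samples)
    illum <- if (augment) stats::runif(n_samples, 0.8, 1.2) else rep(1, n_samples)
    offset <- if (center_jitter) {
      stats::runif(n_samples, -0.5, 0.5) * config$pixel_size_um
    } else rep(0, n_samples)
    src <- sample.int(config$n_sources, n_samples, replace = TRUE)
    prof <- t(vapply(seq_len(n_samples), function(i) {
      p <- .render_transect(r[i], config, defocus_mm = defocus[i],
                            illumination = illum[i], offset_um = offset[i])
      if (config$transect_noise_sd > 0) {
        p <- p + stats::rnorm(120, 0, config$transect_noise_sd * illum[i])
      }
      p
    }, numeric(120)))
    label <- r
    if (label_noise_sd_um > 0) {
      label <- pmax(0, label + stats::rnorm(n_samples, 0, label_noise_sd_um) * (r > 0))
    }
    out <- data.frame(sample_id = seq_len(n_samples),
                      source_id = src,
                      label_um = label,
                      true_radius_um = r,
                      defocus_mm = defocus,
                      illumination = illum)
    colnames(prof) <- sprintf("p%03d", 1:120)
    cbind(out, as.data.frame(prof))
  })
}

#' Render per-edge transect bundles from known radii
#'
#' Plumbing for network-wide radius prediction: for each edge radius, renders
#' `n_per_edge` transects (one per 10-px skeleton segment in the real
#' pipeline) under the configured noise and augmentation model.
#'
#' @param config a [synthetic_run_config()].
#' @param radii_um vector of true per-edge radii.
#' @param n_per_edge transects per edge.
#' @param seed RNG seed.
#' @return data.frame with `edge_id`, `true_radius_um` and profile columns.
#' @export
simulate_edge_transects <- function(config, radii_um, n_per_edge = 5,
                                    seed = config$seed) {
  n <- length(radii_um) * n_per_edge
  d <- generate_transect_dataset(config, n,
                                 empty_fraction = 0, augment = TRUE,
                                 labels_um = rep(radii_um, each = n_per_edge),
                                 seed = seed)
  d$edge_id <- rep(seq_along(radii_um), each = n_per_edge)
  d
}
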