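#' Construct a network snapshot
#'
#' A `network_snapshot` holds the spatial graph of an extraradical mycelium at
#' one timepoint: planar node coordinates (mm), edges with length and radius
#' (um), and spores with radius (um). It is the unit of input for all
#' morphometric observables.
#'
#' @param time_h time since crossing into the fungal compartment, hours.
#' @param nodes data.frame with columns `id`, `x_mm`, `y_mm`.
#' @param edges data.frame with columns `source`, `target`, `length_um`,
#'   `radius_um` (additional columns are kept).
#' @param spores data.frame with columns `x_mm`, `y_mm`, `radius_um`, or NULL.
#' @return an object of class `network_snapshot`.
#' @export
network_snapshot <- function(time_h, nodes, edges, spores = NULL) {
  if (!is.finite(time_h) || time_h < 0) stop("time_h must be non-negative")
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  need_n <- c("id", "x_mm", "y_mm")
  need_e <- c("source", "target", "length_um", "radius_um")
  if (!all(need_n %in% names(nodes))) stop("nodes needs columns: ", paste(need_n, collapse = ", "))
  if (!all(need_e %in% names(edges))) stop("edges needs columns: ", paste(need_e, collapse = ", "))
  if (!all(is.finite(nodes$x_mm)) || !all(is.finite(nodes$y_mm)))
    stop("node coordinates must be finite")
  if (nrow(edges) > 0) {
    if (any(edges$length_um <= 0) || any(edges$radius_um <= 0))
      stop("edge lengths and radii must be > 0")
  }
  if (is.null(spores)) {
    spores <- data.frame(x_mm = numeric(0), y_mm = numeric(0), radius_um = numeric(0))
  } else {
    spores <- as.data.frame(spores)
    if (nrow(spores) > 0 && any(spores$radius_um <= 0)) stop("spore radii must be > 0")
  }
  structure(list(time_h = time_h, nodes = nodes, edges = edges, spores = spores),
            class = "network_snapshot")
}

#' @export
print.network_snapshot <- function(x, ...) {
  cat(sprintf("<network_snapshot t = %g h: %d nodes, %d edges, %d spores>\n",
              x$time_h, nrow(x$nodes), nrow(x$edges), nrow(x$spores)))
  invisible(x)
}

#' Cylinder surface and volume of a hyphal edge
#'
#' Edges are modeled as cylinders: lateral surface `2*pi*r*L` and volume
#' `pi*r^2*L`. Vectorized over edges.
#'
#' @param length_um edge length(s), um.
#' @param radius_um edge radius(s), um.
#' @return list with `surface_um2` and `volume_um3`.
#' @export
edge_surface_volume <- function(length_um, radius_um) {
  stopif_nonpos(length_um, "length_um")
  stopif_nonpos(radius_um, "radius_um")
  list(surface_um2 = 2 * pi * radius_um * length_um,
       volume_um3 = pi * radius_um^2 * length_um)
}

#' Sphere volume of a spore
#'
#' @param radius_um spore radius(s), um.
#' @return volume(s) in um^3, `(4/3)*pi*r^3`.
#' @export
spore_volume <- function(radius_um) {
  stopif_nonpos(radius_um, "radius_um")
  (4 / 3) * pi * radius_um^3
}

#' Convex-hull area and equivalent wave radius of a snapshot
#'
#' The spatial range of the network is measured as the area of the convex hull
#' of its node coordinates; the wave radius is the radius of the disk of equal
#' area, `Rwave = sqrt(A/pi)`.
#'
#' @param snapshot a `network_snapshot`, or a data.frame/matrix of x/y
#'   coordinates in mm.
#' @return list with `area_mm2`, `r_wave_mm` and logical `degenerate` (fewer
#'   than 3 non-collinear points; area is reported as 0).
#' @export
convex_hull_metrics <- function(snapshot) {
  if (inherits(snapshot, "network_snapshot")) {
    xy <- cbind(snapshot$nodes$x_mm, snapshot$nodes$y_mm)
  } else {
    xy <- as.matrix(snapshot)
  }
  xy <- unique(xy[stats::complete.cases(xy), , drop = FALSE])
  if (nrow(xy) < 3) {
    warning("degenerate geometry: fewer than 3 distinct points; area set to 0")
    return(list(area_mm2 = 0, r_wave_mm = 0, degenerate = TRUE))
  }
  h <- grDevices::chull(xy[, 1], xy[, 2])
  hx <- xy[h, 1]; hy <- xy[h, 2]
  # shoelace formula on the hull polygon
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (a <= 0) {
    warning("degenerate geometry: collinear points; area set to 0")
    return(list(area_mm2 = 0, r_wave_mm = 0, degenerate = TRUE))
  }
  list(area_mm2 = a, r_wave_mm = sqrt(a / pi), degenerate = FALSE)
}

#' Totals of a snapshot: hyphal length, surface, volume, and spore volume
#'
#' @param snapshot a `network_snapshot`.
#' @return list with `length_um`, `surface_mm2`, `volume_mm3`,
#'   `spore_volume_mm3`, `n_edges`, `n_spores`.
#' @export
snapshot_totals <- function(snapshot) {
  e <- snapshot$edges
  if (nrow(e) > 0) {
    sv <- edge_surface_volume(e$length_um, e$radius_um)
    L <- sum(e$length_um)
    S <- um2_to_mm2(sum(sv$surface_um2))
    V <- um3_to_mm3(sum(sv$volume_um3))
  } else {
    L <- S <- V <- 0
  }
  Vs <- if (nrow(snapshot$spores) > 0) {
    um3_to_mm3(sum(spore_volume(snapshot$spores$radius_um)))
  } else 0
  list(length_um = L, surface_mm2 = S, volume_mm3 = V, spore_volume_mm3 = Vs,
       n_edges = nrow(e), n_spores = nrow(snapshot$spores))
}

#' Morphometry time series over a snapshot sequence
#'
#' Computes, per timestep, the network totals (L, S, V), convex-hull area A,
#' wave radius, and the spatial densities: hyphal length density
#' `rho = L/A` (um/mm^2), surface density `rho_S = S/A` (dimensionless) and,
#' if carbon parameters are supplied, carbon density `rho_C = Ct/A` (ug/mm^2)
#' where Ct includes both hyphal and spore carbon.
#'
#' @param snapshots list of `network_snapshot` objects.
#' @param carbon optional [carbon_params()] used for `rho_C`.
#' @return data.frame, one row per timestep.
#' @export
morphometry_series <- function(snapshots, carbon = NULL) {
  rows <- lapply(snapshots, function(s) {
    tot <- snapshot_totals(s)
    hull <- suppressWarnings(convex_hull_metrics(s))
    A <- hull$area_mm2
    data.frame(
      t_h = s$time_h,
      n_edges = tot$n_edges,
      n_spores = tot$n_spores,
      length_um = tot$length_um,
      surface_mm2 = tot$surface_mm2,
      volume_mm3 = tot$volume_mm3,
      spore_volume_mm3 = tot$spore_volume_mm3,
      area_mm2 = A,
      r_wave_mm = hull$r_wave_mm,
      rho_um_mm2 = if (A > 0) tot$length_um / A else NA_real_,
      rho_S = if (A > 0) tot$surface_mm2 / A else NA_real_,
      rho_C_ug_mm2 = if (!is.null(carbon) && A > 0) {
        carbon$MC_ug_mm3 * (tot$volume_mm3 + tot$spore_volume_mm3) / A
      } else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$t_h), , drop = FALSE]
}

#' Traveling-wave speed from a wave-radius time series
#'
#' Ordinary least-squares fit of `Rwave` (mm) against time (h) over a time
#' window; the slope, converted to um/h, estimates the range-expansion speed.
#'
#' @param times_h time vector, hours.
#' @param r_wave_mm wave radius vector, mm.
#' @param window optional numeric length-2 `c(t_min, t_max)` restricting the
#'   fit; default uses all points.
#' @return list with `v_wave_um_h`, `r_squared`, `n`, `intercept_mm`.
#' @export
wave_speed <- function(times_h, r_wave_mm, window = NULL) {
  keep <- is.finite(times_h) & is.finite(r_wave_mm)
  if (!is.null(window)) keep <- keep & times_h >= window[1] & times_h <= window[2]
  t <- times_h[keep]; r <- r_wave_mm[keep]
  if (length(t) < 3) stop("wave_speed needs at least 3 timepoints in the window")
  fit <- stats::lm(r ~ t)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((r - mean(r))^2)
  list(v_wave_um_h = unname(stats::coef(fit)[2]) * 1e3,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n = length(t),
       intercept_mm = unname(stats::coef(fit)[1]))
}

#' Radius distribution of network edges
#'
#' Histogram and cumulative distribution of per-edge radii, either
#' count-weighted or volume-weighted (each edge contributes `pi*r^2*L`). The
#' volume-weighted CDF gives, for each radius, the proportion of total network
#' volume contributed by edges at or below that radius.
#'
#' @param snapshot a `network_snapshot`.
#' @param weighting `"count"` or `"volume"`.
#' @param breaks histogram bin edges (um); default `seq(0, 8, by = 0.25)`
#'   extended to cover the data.
#' @return list with `histogram` (data.frame: bin_lo, bin_hi, mass), `cdf`
#'   (data.frame: radius_um, cum_mass), `weighting`, and `empty` flag.
#' @export
radius_distribution <- function(snapshot, weighting = c("count", "volume"),
                                breaks = NULL) {
  weighting <- match.arg(weighting)
  e <- snapshot$edges
  if (nrow(e) == 0) {
    return(list(histogram = data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                                       mass = numeric(0)),
                cdf = data.frame(radius_um = numeric(0), cum_mass = numeric(0)),
                weighting = weighting, empty = TRUE))
  }
  r <- e$radius_um
  w <- if (weighting == "volume") pi * r^2 * e$length_um else rep(1, length(r))
  w <- w / sum(w)
  if (is.null(breaks)) {
    hi <- max(8, ceiling(max(r) * 4) / 4)
    breaks <- seq(0, hi, by = 0.25)
  }
  if (max(r) > max(breaks) || min(r) < min(breaks)) stop("breaks do not cover the data")
  bin <- cut(r, breaks = breaks, include.lowest = TRUE, right = TRUE)
  mass <- tapply(w, bin, sum, default = 0)
  hist_df <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                        mass = as.numeric(mass))
  o <- order(r)
  cdf <- data.frame(radius_um = r[o], cum_mass = cumsum(w[o]))
  cdf <- cdf[!duplicated(cdf$radius_um, fromLast = TRUE), , drop = FALSE]
  list(histogram = hist_df, cdf = cdf, weighting = weighting, empty = FALSE)
}
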