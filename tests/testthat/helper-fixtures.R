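# Shared fixture builders. Everything is generated in code under fixed seeds.

quick_config <- function(seed = 1, ...) {
  synthetic_run_config(seed = seed, duration_h = 100, sampling_interval_h = 4, ...)
}

clean_config <- function(seed = 1, ...) {
  # noise-free variant for exact-arithmetic checks
  synthetic_run_config(seed = seed, duration_h = 100, sampling_interval_h = 4,
                       assay_noise_sd_ug = 0, transect_noise_sd = 0,
                       psf_sigma_um = 0, replicate_cv = 0, ...)
}

# a tiny hand-built snapshot: two edges, one spore, nodes on a unit square
toy_snapshot <- function(time_h = 10) {
  nodes <- data.frame(id = c("a", "b", "c", "d"),
                      x_mm = c(0, 1, 1, 0), y_mm = c(0, 0, 1, 1))
  edges <- data.frame(source = c("a", "b"), target = c("b", "c"),
                      length_um = c(1000, 500), radius_um = c(2, 3))
  spores <- data.frame(x_mm = 0.5, y_mm = 0.5, radius_um = 40)
  network_snapshot(time_h, nodes, edges, spores)
}

# O(n^3) brute-force convex hull area: every pair of points is tested as a
# hull edge (all remaining points strictly on one side); vertices are ordered
# by angle around the centroid and the polygon area taken by the shoelace rule.
brute_hull_area <- function(xy) {
  n <- nrow(xy)
  on_hull <- rep(FALSE, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- xy[j, ] - xy[i, ]
    cr <- (xy[, 1] - xy[i, 1]) * d[2] - (xy[, 2] - xy[i, 2]) * d[1]
    if (all(cr <= 1e-12) || all(cr >= -1e-12)) on_hull[c(i, j)] <- TRUE
  }
  h <- xy[on_hull, , drop = FALSE]
  cen <- colMeans(h)
  o <- order(atan2(h[, 2] - cen[2], h[, 1] - cen[1]))
  h <- h[o, , drop = FALSE]
  x <- h[, 1]; y <- h[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

fast_wave_params <- function(...) {
  wave_model_params(dR_mm = 0.2, ...)
}
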