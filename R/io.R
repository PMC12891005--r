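#' Write a snapshot sequence as paired CSV tables
#'
#' One trio of files per timestep (`nodes_<i>.csv`, `edges_<i>.csv`,
#' `spores_<i>.csv`) plus an `index.csv` mapping timesteps to files.
#' Node schema: `id,x_mm,y_mm`; edge schema:
#' `source,target,length_um,radius_um`; spore schema: `x_mm,y_mm,radius_um`.
#'
#' @param snapshots list of `network_snapshot`.
#' @param dir output directory (created if needed).
#' @return invisibly, the index data.frame.
#' @export
write_snapshots <- function(snapshots, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(step = seq_along(snapshots),
                    t_h = vapply(snapshots, function(s) s$time_h, numeric(1)))
  idx$nodes <- sprintf("nodes_%04d.csv", idx$step)
  idx$edges <- sprintf("edges_%04d.csv", idx$step)
  idx$spores <- sprintf("spores_%04d.csv", idx$step)
  for (i in seq_along(snapshots)) {
    s <- snapshots[[i]]
    utils::write.csv(s$nodes, file.path(dir, idx$nodes[i]), row.names = FALSE)
    utils::write.csv(s$edges, file.path(dir, idx$edges[i]), row.names = FALSE)
    utils::write.csv(s$spores, file.path(dir, idx$spores[i]), row.names = FALSE)
  }
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' Read a snapshot sequence written by [write_snapshots()]
#'
#' @param dir directory holding `index.csv` and the per-timestep tables.
#' @return list of `network_snapshot`.
#' @export
read_snapshots <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"))
  lapply(seq_len(nrow(idx)), function(i) {
    network_snapshot(
      idx$t_h[i],
      utils::read.csv(file.path(dir, idx$nodes[i])),
      utils::read.csv(file.path(dir, idx$edges[i])),
      utils::read.csv(file.path(dir, idx$spores[i]))
    )
  })
}
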