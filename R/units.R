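# Package-wide units convention:
#   edge lengths and radii ........ um
#   node coordinates, grid radii .. mm
#   areas ......................... mm^2
#   volumes ....................... mm^3 (gel volume in mL = cm^3)
#   time .......................... hours
#   masses ........................ ug
#   P uptake coefficient J ........ ng mm^-2 h^-1
#   concentrations ................ ug/mL
# All conversions are centralized here.

UM2_PER_MM2 <- 1e6
UM3_PER_MM3 <- 1e9
NG_PER_UG <- 1e3
MM3_PER_ML <- 1e3

um2_to_mm2 <- function(x) x / UM2_PER_MM2
um3_to_mm3 <- function(x) x / UM3_PER_MM3
ng_to_ug <- function(x) x / NG_PER_UG
ug_per_ml_to_ug_per_mm3 <- function(x) x / MM3_PER_ML

#' @keywords internal
#' Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopif_nonpos <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be finite and > 0", call. = FALSE)
  }
  invisible(TRUE)
}
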