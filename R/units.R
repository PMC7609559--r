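#' Unit conventions
#'
#' Clinical hemodynamics mixes unit systems: cuff and transstenotic pressures
#' are reported in mmHg, flows in ml/s, shear stresses in Pa. All internal
#' computation in this package is SI (Pa, m3/s, m); these constants and
#' helpers define the boundary conversions.
#'
#' @format A list with elements `pa_per_mmhg` (133.322 Pa per mmHg) and
#'   `m3s_per_mls` (1e-6 m3/s per ml/s).
#' @export
unit_conventions <- list(
  pa_per_mmhg = 133.322,
  m3s_per_mls = 1e-6
)

#' Convert pressures between mmHg and Pa
#'
#' Exact linear conversion by 133.322 Pa per mmHg.
#'
#' @param value numeric vector of pressures.
#' @param from,to unit names, each one of `"mmHg"` or `"Pa"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_pressure(20, "mmHg", "Pa")   # 2666.44
#' convert_pressure(0, "Pa", "mmHg")    # 0
#' @export
convert_pressure <- function(value, from, to) {
  units <- c("mmHg", "Pa")
  if (!(from %in% units) || !(to %in% units)) {
    stop("unknown pressure unit: units must be 'mmHg' or 'Pa'", call. = FALSE)
  }
  if (from == to) return(value)
  if (from == "mmHg") value * unit_conventions$pa_per_mmhg
  else value / unit_conventions$pa_per_mmhg
}

#' Convert volumetric flow between ml/s and m3/s
#'
#' @param value numeric vector of flows.
#' @param from,to unit names, each one of `"ml/s"` or `"m3/s"`.
#' @return numeric vector in the target unit.
#' @export
convert_flow <- function(value, from, to) {
  units <- c("ml/s", "m3/s")
  if (!(from %in% units) || !(to %in% units)) {
    stop("unknown flow unit: units must be 'ml/s' or 'm3/s'", call. = FALSE)
  }
  if (from == to) return(value)
  if (from == "ml/s") value * unit_conventions$m3s_per_mls
  else value / unit_conventions$m3s_per_mls
}
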