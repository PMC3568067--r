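#' Cardiomyocyte cell volume
#'
#' Cylinder approximation V = pi/4 d^2 l. With the standard human
#' cardiomyocyte dimensions (diameter 14 um, length 140 um) this gives
#' 2.16e-11 litres, the reference volume to which all fluxes in this
#' package are anchored (mmol.min^-1.(l cell)^-1).
#'
#' @param d_um cell diameter in micrometres (> 0).
#' @param l_um cell length in micrometres (> 0).
#' @return volume in litres.
#' @export
cardiomyocyte_volume <- function(d_um = 14, l_um = 140) {
  if (any(d_um <= 0) || any(l_um <= 0))
    stop("cell dimensions must be positive")
  pi / 4 * (d_um * 1e-6)^2 * (l_um * 1e-6) * 1000  # m^3 -> l
}

#' Convert a per-cell rate to a per-litre-of-cell rate
#'
#' @param rate_per_cell rate in mmol.min^-1.cell^-1.
#' @param volume_l cell volume in litres (> 0).
#' @return rate in mmol.min^-1.(l cell)^-1.
#' @export
per_cell_to_per_liter <- function(rate_per_cell, volume_l) {
  if (any(volume_l <= 0)) stop("cell volume must be positive")
  rate_per_cell / volume_l
}

#' Inverse of [per_cell_to_per_liter()]
#'
#' @param rate_per_liter rate in mmol.min^-1.(l cell)^-1.
#' @param volume_l cell volume in litres (> 0).
#' @return rate in mmol.min^-1.cell^-1.
#' @export
per_liter_to_per_cell <- function(rate_per_liter, volume_l) {
  if (any(volume_l <= 0)) stop("cell volume must be positive")
  rate_per_liter * volume_l
}
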