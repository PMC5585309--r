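# Myelination metrics and conduction-velocity estimates for thin
# intracortical axons.

#' g-ratio of a myelinated fiber
#'
#' Axon diameter divided by total fiber diameter (axon plus myelin):
#' g = (total - 2 x sheath) / total. Undefined for unmyelinated
#' fibers. Scale-invariant: multiplying both measurements by a common
#' factor leaves g unchanged, so fixation shrinkage does not affect it.
#'
#' @param total_diameter_um outer fiber diameter (axon + myelin).
#' @param sheath_thickness_um myelin sheath thickness per side.
#' @param myelinated logical; must be TRUE for g to be defined.
#' @return g-ratio in (0, 1].
#' @export
g_ratio <- function(total_diameter_um, sheath_thickness_um,
                    myelinated = TRUE) {
  if (!myelinated) stop("g-ratio undefined for unmyelinated fibers")
  stopifnot(total_diameter_um > 0, sheath_thickness_um >= 0)
  if (2 * sheath_thickness_um >= total_diameter_um) {
    stop("sheath thickness must be < total diameter / 2")
  }
  (total_diameter_um - 2 * sheath_thickness_um) / total_diameter_um
}

#' Conduction velocity of a thin myelinated axon
#'
#' Empirical linear diameter-velocity relation for myelinated CNS
#' fibers: velocity = 5.5 m/s per micrometre of total fiber diameter.
#'
#' @param total_diameter_um total fiber diameter in micrometres (>= 0).
#' @param slope_ms_per_um slope of the relation (default 5.5).
#' @return velocity in m/s.
#' @export
conduction_velocity_myelinated <- function(total_diameter_um,
                                           slope_ms_per_um = 5.5) {
  stopifnot(all(total_diameter_um >= 0))
  slope_ms_per_um * total_diameter_um
}

#' Conduction velocity of an unmyelinated axon of the same diameter
#'
#' Taken as a fixed fraction slower than the myelinated estimate
#' (default penalty 15 percent).
#'
#' @param total_diameter_um fiber diameter in micrometres.
#' @param penalty fractional slowdown in [0, 1).
#' @param slope_ms_per_um slope of the myelinated relation.
#' @return velocity in m/s.
#' @export
conduction_velocity_unmyelinated <- function(total_diameter_um,
                                             penalty = 0.15,
                                             slope_ms_per_um = 5.5) {
  if (penalty < 0 || penalty >= 1) stop("penalty must lie in [0, 1)")
  (1 - penalty) * conduction_velocity_myelinated(total_diameter_um,
                                                 slope_ms_per_um)
}

#' Correct a measurement for fixation shrinkage
#'
#' Divides by (1 - fraction)^power: power 1 for lengths/diameters,
#' 2 for areas, 3 for volumes. The default 11 percent is the linear
#' shrinkage typical of aldehyde-fixed, resin-embedded cortex.
#'
#' @param value measured value (in fixed tissue).
#' @param fraction linear shrinkage fraction in [0, 1) (default 0.11).
#' @param power 1 (length), 2 (area) or 3 (volume).
#' @return shrinkage-corrected value.
#' @export
shrinkage_correct <- function(value, fraction = 0.11, power = 1L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  stopifnot(power %in% c(1L, 2L, 3L))
  value / (1 - fraction)^power
}

#' Transit time over a conduction distance
#'
#' @param distance_mm distance in millimetres.
#' @param velocity_ms velocity in m/s (> 0).
#' @return transit time in milliseconds.
#' @export
transit_time_ms <- function(distance_mm, velocity_ms) {
  stopifnot(all(velocity_ms > 0))
  distance_mm / velocity_ms
}
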