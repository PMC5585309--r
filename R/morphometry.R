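# Serial-section morphometry: PSD area, spine volume, dendrite radius,
# spiny/smooth classification.

# length of an open polyline given as an n x 2 vertex matrix
polyline_length <- function(v) {
  if (nrow(v) < 2L) return(0)
  sum(sqrt(diff(v[, 1])^2 + diff(v[, 2])^2))
}

# absolute area of a simple polygon (pracma::polyarea is signed)
polygon_area <- function(v) {
  abs(pracma::polyarea(v[, 1], v[, 2]))
}

#' Postsynaptic density area from serial traces
#'
#' The PSD is treated as a thin surface sampled by one linear profile
#' per section: the area estimate is the sum over sections of trace arc
#' length times section thickness, the standard stereological surface
#' estimator for structures traced as linear profiles. The estimator is
#' consistent for surfaces roughly perpendicular to the section plane
#' and underestimates strongly oblique surface patches.
#'
#' @param stack a [contour_stack()] containing at least one
#'   \code{psd_trace} contour.
#' @return PSD area in square micrometres.
#' @export
psd_area <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  tr <- Filter(function(ct) ct$kind == "psd_trace", stack$contours)
  if (!length(tr)) stop("no psd_trace contours in stack")
  t_um <- stack$section_nm / 1000
  sum(vapply(tr, function(ct) polyline_length(ct$vertices), numeric(1))) * t_um
}

#' Spine (or dendrite) volume by the Cavalieri principle
#'
#' Sum of cross-section polygon areas times section thickness; exact
#' for prisms, and accurate to the discretisation error of the section
#' spacing for smooth shapes.
#'
#' @param stack a [contour_stack()] containing at least one
#'   \code{cross_section} contour.
#' @return volume in cubic micrometres.
#' @export
spine_volume <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  cs <- Filter(function(ct) ct$kind == "cross_section", stack$contours)
  if (!length(cs)) stop("no cross_section contours in stack")
  t_um <- stack$section_nm / 1000
  sum(vapply(cs, function(ct) polygon_area(ct$vertices), numeric(1))) * t_um
}

#' Mean equivalent-circle radius of a dendrite
#'
#' Per cross-section the equivalent-circle radius sqrt(A / pi) is
#' computed from the polygon area A; the dendrite radius is the mean
#' over sections. Requires at least 3 cross-sections for a stable
#' average.
#'
#' @param stack a [contour_stack()] with >= 3 \code{cross_section}
#'   contours.
#' @return radius in micrometres.
#' @export
dendrite_radius <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  cs <- Filter(function(ct) ct$kind == "cross_section", stack$contours)
  if (length(cs) < 3L) stop("need at least 3 cross_sections")
  mean(vapply(cs, function(ct) sqrt(polygon_area(ct$vertices) / pi),
              numeric(1)))
}

#' Classify a reconstructed dendrite segment as spiny or smooth
#'
#' Smooth (putative GABAergic) dendrites lack spines and carry a dense
#' load of asymmetric shaft synapses; spiny dendrites are recognised by
#' their spines. The default thresholds (spine density >= 0.1 per
#' micrometre for spiny; zero spines and asymmetric shaft-synapse
#' density >= 0.5 per micrometre for smooth; minimum assessable length
#' 2 micrometres) implement that criterion on short reconstructed
#' segments; segments matching neither rule, or too short to assess,
#' are \code{unclassified} - a first-class outcome mirroring the
#' limited traceability of real serial-section material.
#'
#' @param length_um segment length (> 0).
#' @param spine_count number of spines on the segment.
#' @param shaft_asymmetric_synapse_count asymmetric synapses on the
#'   shaft.
#' @param min_length_um,spiny_density_per_um,smooth_synapse_density_per_um
#'   classification thresholds.
#' @return list with \code{class} in
#'   \code{{spiny, smooth, unclassified}} and \code{reason}.
#' @export
classify_dendrite <- function(length_um, spine_count,
                              shaft_asymmetric_synapse_count,
                              min_length_um = 2,
                              spiny_density_per_um = 0.1,
                              smooth_synapse_density_per_um = 0.5) {
  stopifnot(length_um > 0, spine_count >= 0,
            shaft_asymmetric_synapse_count >= 0)
  if (length_um < min_length_um) {
    return(list(class = "unclassified",
                reason = sprintf("segment shorter than %.3g um assessable minimum",
                                 min_length_um)))
  }
  spine_density <- spine_count / length_um
  shaft_density <- shaft_asymmetric_synapse_count / length_um
  if (spine_density >= spiny_density_per_um) {
    return(list(class = "spiny", reason = "spine-bearing"))
  }
  if (spine_count == 0 && shaft_density >= smooth_synapse_density_per_um) {
    return(list(class = "smooth",
                reason = "spine-free shaft densely covered with asymmetric synapses"))
  }
  list(class = "unclassified", reason = "matches neither criterion")
}

#' Rescale a contour stack in all three dimensions
#'
#' Multiplies all vertex coordinates and the section thickness by `s`;
#' areas scale as s^2 and volumes as s^3. Used for shrinkage
#' correction at the input stage (see [shrinkage_correct()]).
#'
#' @param stack a [contour_stack()].
#' @param s positive scale factor.
#' @return rescaled [contour_stack()].
#' @export
scale_contour_stack <- function(stack, s) {
  stopifnot(inherits(stack, "contour_stack"), s > 0)
  contours <- lapply(stack$contours, function(ct) {
    ct$vertices <- ct$vertices * s
    ct
  })
  contour_stack(contours, stack$section_nm * s)
}
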