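#' Orientation-preference map
#'
#' Container for an orientation-preference map on a metric pixel grid:
#' a per-pixel preferred stimulus orientation in degrees (half-open
#' interval \code{[0, 180)}; 0/180 horizontal, 90 vertical) and a
#' non-negative tuning magnitude in arbitrary units. Pixels where the
#' preference is undefined (zero resultant) carry magnitude 0 and
#' angle \code{NA}.
#'
#' @param angle_deg numeric matrix of preferred orientations in degrees.
#' @param magnitude numeric matrix of tuning magnitudes, same dimensions.
#' @param pixel_um positive scalar, pixel edge length in micrometres.
#' @return an object of class \code{orientation_map}.
#' @export
orientation_map <- function(angle_deg, magnitude, pixel_um) {
  if (!is.matrix(angle_deg) || !is.matrix(magnitude)) {
    stop("angle_deg and magnitude must be matrices")
  }
  if (!identical(dim(angle_deg), dim(magnitude))) {
    stop("angle and magnitude grids must be congruent")
  }
  if (!is.numeric(pixel_um) || length(pixel_um) != 1L || pixel_um <= 0) {
    stop("pixel_um must be a positive scalar")
  }
  if (any(magnitude < 0, na.rm = TRUE)) stop("magnitude must be >= 0")
  finite <- !is.na(angle_deg)
  if (any(angle_deg[finite] < 0 | angle_deg[finite] >= 180)) {
    stop("angles must lie in [0, 180)")
  }
  structure(
    list(angle_deg = angle_deg, magnitude = magnitude,
         pixel_um = as.numeric(pixel_um)),
    class = "orientation_map"
  )
}

#' @export
print.orientation_map <- function(x, ...) {
  d <- dim(x$angle_deg)
  cat(sprintf("orientation_map: %d x %d px, %.3g um/px (%.3g x %.3g um)\n",
              d[1], d[2], x$pixel_um, d[1] * x$pixel_um, d[2] * x$pixel_um))
  invisible(x)
}

#' Stack of single-condition response images
#'
#' Holds one response image per stimulus orientation, e.g. the eight
#' grating orientations 0, 22.5, ..., 157.5 degrees used in
#' intrinsic-signal imaging protocols.
#'
#' @param stimulus_angles_deg numeric vector of stimulus orientations
#'   (degrees; must be distinct modulo 180).
#' @param responses list of numeric matrices, one per angle, all congruent.
#' @return an object of class \code{condition_stack}.
#' @export
condition_stack <- function(stimulus_angles_deg, responses) {
  if (length(stimulus_angles_deg) != length(responses)) {
    stop("one response grid per stimulus angle required")
  }
  if (length(responses) < 1L) stop("at least one condition required")
  dims <- lapply(responses, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all response grids must be congruent")
  }
  a <- wrap180(stimulus_angles_deg)
  if (anyDuplicated(round(a, 9))) {
    stop("stimulus angles must be distinct modulo 180")
  }
  structure(
    list(stimulus_angles_deg = as.numeric(stimulus_angles_deg),
         responses = responses),
    class = "condition_stack"
  )
}

#' Cocktail-blank single-condition map
#'
#' Normalises the response image of one stimulus orientation by the
#' summed response to all stimuli (the "cocktail blank"), the standard
#' single-map construction in intrinsic-signal imaging. With
#' \code{divisor = "orthogonal"} the differential variant is computed
#' instead: the response is divided by the response to the orthogonal
#' orientation.
#'
#' @param stack a [condition_stack()].
#' @param angle_deg stimulus orientation whose map is requested; must be
#'   one of the stack's angles.
#' @param divisor \code{"cocktail"} (default) or \code{"orthogonal"}.
#' @return numeric matrix of normalised responses.
#' @export
cocktail_blank_map <- function(stack, angle_deg,
                               divisor = c("cocktail", "orthogonal")) {
  divisor <- match.arg(divisor)
  stopifnot(inherits(stack, "condition_stack"))
  idx <- which(abs(acute_orientation_diff(stack$stimulus_angles_deg,
                                          angle_deg)) < 1e-9)
  if (length(idx) != 1L) stop("requested angle not present in stack")
  num <- stack$responses[[idx]]
  if (divisor == "cocktail") {
    den <- Reduce(`+`, stack$responses)
  } else {
    oidx <- which(abs(acute_orientation_diff(stack$stimulus_angles_deg,
                                             angle_deg + 90)) < 1e-9)
    if (length(oidx) != 1L) stop("orthogonal condition not present in stack")
    den <- stack$responses[[oidx]]
  }
  bad <- which(den == 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(den))
    stop(sprintf("zero denominator at pixel (row %d, col %d)%s",
                 rc[1], rc[2],
                 if (length(bad) > 1) sprintf(" and %d more", length(bad) - 1)
                 else ""))
  }
  num / den
}

#' Orientation-preference map by vector averaging
#'
#' Computes, per pixel, the vector sum of the condition responses on
#' doubled stimulus angles: \eqn{R = \sum_k r_k e^{i 2\theta_k}}. The
#' preferred orientation is \eqn{\arg(R)/2}, mapped to \code{[0, 180)};
#' the magnitude is \eqn{|R| / \sum_k r_k} (ratio-normalised, hence
#' invariant to scaling all responses by a positive constant). Pixels
#' with zero resultant (e.g. equal responses to all orientations) get
#' magnitude 0 and angle \code{NA}.
#'
#' @param stack a [condition_stack()] with at least two distinct angles.
#' @param pixel_um pixel size in micrometres for the resulting map.
#' @return an [orientation_map()].
#' @export
preference_map <- function(stack, pixel_um = 1) {
  stopifnot(inherits(stack, "condition_stack"))
  if (length(stack$responses) < 2L) {
    stop("at least two distinct stimulus angles required")
  }
  dims <- dim(stack$responses[[1]])
  re <- matrix(0, dims[1], dims[2])
  im <- matrix(0, dims[1], dims[2])
  tot <- matrix(0, dims[1], dims[2])
  for (k in seq_along(stack$responses)) {
    th2 <- 2 * stack$stimulus_angles_deg[k] * pi / 180
    r <- stack$responses[[k]]
    re <- re + r * cos(th2)
    im <- im + r * sin(th2)
    tot <- tot + r
  }
  mag_raw <- sqrt(re^2 + im^2)
  magnitude <- ifelse(tot > 0, mag_raw / tot, 0)
  angle <- wrap180(atan2(im, re) / 2 * 180 / pi)
  undef <- mag_raw < .Machine$double.eps^0.5 * pmax(tot, 1)
  angle[undef] <- NA_real_
  magnitude[undef] <- 0
  orientation_map(angle, magnitude, pixel_um)
}

#' Sample a map at metric point positions
#'
#' Nearest-pixel lookup (no interpolation, bit-reproducible): the point
#' (x, y) in micrometres falls in the pixel whose row is
#' \code{floor(y / pixel_um) + 1} and column \code{floor(x / pixel_um) + 1};
#' x runs along columns, y along rows, origin at the map corner.
#'
#' @param map an [orientation_map()].
#' @param points_um numeric matrix with columns x, y (micrometres); zero
#'   rows allowed.
#' @return data.frame with columns \code{angle_deg}, \code{magnitude},
#'   one row per point, order preserved.
#' @export
sample_map <- function(map, points_um) {
  stopifnot(inherits(map, "orientation_map"))
  points_um <- as.matrix(points_um)
  if (nrow(points_um) == 0L) {
    return(data.frame(angle_deg = numeric(0), magnitude = numeric(0)))
  }
  if (ncol(points_um) < 2L) stop("points_um must have columns x, y")
  d <- dim(map$angle_deg)
  col <- floor(points_um[, 1] / map$pixel_um) + 1L
  row <- floor(points_um[, 2] / map$pixel_um) + 1L
  out <- which(col < 1L | col > d[2] | row < 1L | row > d[1])
  if (length(out)) {
    stop(sprintf("points outside map extent at indices: %s",
                 paste(utils::head(out, 10), collapse = ", ")))
  }
  idx <- cbind(row, col)
  data.frame(angle_deg = map$angle_deg[idx], magnitude = map$magnitude[idx])
}
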