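#' Point sample on an orientation map
#'
#' A non-empty set of 2D positions (micrometres) belonging either to a
#' dendritic tree or to a bouton cluster, used to define the orientation
#' domain occupied by that structure.
#'
#' @param positions_um n x 2 numeric matrix (x, y in micrometres), n >= 1.
#' @param label \code{"dendrites"} or \code{"cluster"}.
#' @param cluster_kind \code{"local"}, \code{"distal"} or \code{"none"}.
#' @return object of class \code{point_sample}.
#' @export
point_sample <- function(positions_um, label = c("dendrites", "cluster"),
                         cluster_kind = c("none", "local", "distal")) {
  label <- match.arg(label)
  cluster_kind <- match.arg(cluster_kind)
  positions_um <- as.matrix(positions_um)
  if (nrow(positions_um) < 1L || ncol(positions_um) != 2L) {
    stop("positions_um must be a non-empty n x 2 matrix")
  }
  structure(list(positions_um = positions_um, label = label,
                 cluster_kind = cluster_kind),
            class = "point_sample")
}

#' Orientation domain of a point sample
#'
#' The domain angle is the magnitude-weighted circular mean of the map
#' orientations sampled at the points, computed on doubled angles
#' (orientations have period 180 degrees): with sampled angles
#' \eqn{\theta_j} and magnitudes \eqn{w_j}, the domain angle is
#' \eqn{\frac{1}{2}\arg\sum_j w_j e^{i2\theta_j}}, mapped to
#' \code{[0, 180)}. An error is raised when the resultant vanishes
#' (e.g. two equal-weight pixels exactly 90 degrees apart) or all
#' sampled magnitudes are zero: the domain is then undefined.
#'
#' @param map an [orientation_map()].
#' @param sample a [point_sample()] (or bare n x 2 position matrix).
#' @return domain angle in degrees, in \code{[0, 180)}.
#' @export
domain_angle <- function(map, sample) {
  pos <- if (inherits(sample, "point_sample")) sample$positions_um
         else as.matrix(sample)
  sm <- sample_map(map, pos)
  ok <- !is.na(sm$angle_deg)
  if (!any(ok) || sum(sm$magnitude[ok]) <= 0) {
    stop("undefined domain: all sampled magnitudes are zero")
  }
  th2 <- 2 * sm$angle_deg[ok] * pi / 180
  w <- sm$magnitude[ok]
  re <- sum(w * cos(th2)); im <- sum(w * sin(th2))
  if (sqrt(re^2 + im^2) < .Machine$double.eps^0.5 * sum(w)) {
    stop("undefined domain: zero resultant (antipodal cancellation)")
  }
  wrap180(atan2(im, re) / 2 * 180 / pi)
}

#' Similarity Index between dendritic and cluster orientation domains
#'
#' SI = 1 - delta/90, where delta is the acute angular difference (at
#' most 90 degrees, orientations having period 180) between the domain
#' angles of the two samples. SI = 1 means identical orientation
#' tuning of the two domains; SI = 0 means the cluster lies in a domain
#' tuned 90 degrees to the dendrites' domain. Symmetric in its two
#' samples and invariant under joint rotation of both domains.
#'
#' @param map an [orientation_map()].
#' @param dendrites,cluster [point_sample()]s (or position matrices).
#' @return SI in \code{[0, 1]}.
#' @export
similarity_index <- function(map, dendrites, cluster) {
  a <- domain_angle(map, dendrites)
  b <- domain_angle(map, cluster)
  1 - acute_orientation_diff(a, b) / 90
}

#' Classify a Similarity Index into the extreme bands
#'
#' Clusters are called \code{similar} when SI > 0.65, \code{dissimilar}
#' when SI < 0.35, and \code{intermediate} otherwise; the analysis of
#' target composition uses only the two extremes.
#'
#' @param si numeric SI value(s) in \code{[0, 1]}.
#' @return character vector in \code{{similar, dissimilar, intermediate}}.
#' @export
classify_si <- function(si) {
  if (any(si < 0 | si > 1, na.rm = TRUE)) stop("si must lie in [0, 1]")
  out <- rep("intermediate", length(si))
  out[si > 0.65] <- "similar"
  out[si < 0.35] <- "dissimilar"
  out[is.na(si)] <- NA_character_
  out
}
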