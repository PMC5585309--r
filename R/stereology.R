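#' Serial-section synapse profile stack
#'
#' One row per synapse profile: \code{section} (integer index, ordered
#' in z), \code{id} (synapse identifier; one synapse may appear in
#' several consecutive sections), \code{x, y} (profile centroid,
#' micrometres), \code{type} (\code{asymmetric}/\code{symmetric}),
#' \code{target} (\code{spine}/\code{shaft}/\code{soma}) and
#' \code{class} (\code{spiny}/\code{smooth}/\code{unknown}).
#'
#' @param profiles data.frame with the columns above.
#' @param section_thickness_nm section thickness (default 50, the
#'   standard for disector pairs; resectioned material uses 60).
#' @param n_sections physical number of sections in the series (a
#'   section may carry no profile); defaults to the largest section
#'   index observed.
#' @return object of class \code{section_stack}.
#' @export
section_stack <- function(profiles, section_thickness_nm = 50,
                          n_sections = max(profiles$section)) {
  need <- c("section", "id", "x", "y", "type", "target", "class")
  if (!all(need %in% names(profiles))) {
    stop("profiles must have columns: ", paste(need, collapse = ", "))
  }
  stopifnot(section_thickness_nm > 0, n_sections >= max(profiles$section))
  dup <- duplicated(profiles[, c("section", "id")])
  if (any(dup)) stop("a synapse may have at most one profile per section")
  profiles <- profiles[order(profiles$section), need]
  rownames(profiles) <- NULL
  structure(list(profiles = profiles,
                 section_thickness_nm = section_thickness_nm,
                 n_sections = as.integer(n_sections)),
            class = "section_stack")
}

#' Physical-disector counting frame
#'
#' Rectangular unbiased counting frame applied to a reference/lookup
#' section pair separated by one intervening section
#' (\code{lookup_index - reference_index = 2}).
#'
#' @param width_um,height_um frame size in micrometres.
#' @param offset_um length-2 numeric, lower-left frame corner.
#' @param reference_index,lookup_index section indices of the pair.
#' @return object of class \code{disector_frame}.
#' @export
disector_frame <- function(width_um, height_um, offset_um = c(0, 0),
                           reference_index, lookup_index = reference_index + 2L) {
  stopifnot(width_um > 0, height_um > 0, length(offset_um) == 2L)
  if (lookup_index - reference_index != 2L) {
    stop("lookup and reference must be separated by one intervening section")
  }
  structure(list(width_um = width_um, height_um = height_um,
                 offset_um = as.numeric(offset_um),
                 reference_index = as.integer(reference_index),
                 lookup_index = as.integer(lookup_index)),
            class = "disector_frame")
}

# unbiased counting-frame rule for profile centroids: include points on
# the inclusion edges (top/right), exclude the exclusion edges
# (bottom/left): x in (x0, x0 + w], y in (y0, y0 + h]
in_frame <- function(x, y, frame) {
  x0 <- frame$offset_um[1]; y0 <- frame$offset_um[2]
  x > x0 & x <= x0 + frame$width_um & y > y0 & y <= y0 + frame$height_um
}

#' Physical-disector count
#'
#' Counts synapses with a profile inside the counting frame in the
#' reference section and no profile in the lookup section (Q-minus);
#' with \code{bidirectional = TRUE} both sections of the pair serve as
#' reference and lookup in turn, doubling the number of disectors.
#' Tallies are broken down by synapse target and type.
#'
#' @param stack a [section_stack()].
#' @param frame a [disector_frame()]; both its section indices must
#'   exist in the stack's section range.
#' @param bidirectional count both directions (default FALSE).
#' @return list with \code{q_minus}, \code{by_target}, \code{by_type},
#'   \code{ids} (counted synapse ids) and \code{n_directions}.
#' @export
disector_count <- function(stack, frame, bidirectional = FALSE) {
  stopifnot(inherits(stack, "section_stack"), inherits(frame, "disector_frame"))
  if (frame$reference_index < 1L || frame$lookup_index > stack$n_sections) {
    stop("frame section pair outside the stack's section range")
  }
  one_dir <- function(ref, look) {
    p <- stack$profiles
    in_ref <- p[p$section == ref & in_frame(p$x, p$y, frame), , drop = FALSE]
    look_ids <- unique(p$id[p$section == look])
    in_ref[!(in_ref$id %in% look_ids), , drop = FALSE]
  }
  hits <- one_dir(frame$reference_index, frame$lookup_index)
  if (bidirectional) {
    hits <- rbind(hits, one_dir(frame$lookup_index, frame$reference_index))
  }
  list(q_minus = nrow(hits),
       by_target = table(factor(hits$target,
                                levels = c("spine", "shaft", "soma"))),
       by_type = table(factor(hits$type,
                              levels = c("asymmetric", "symmetric"))),
       ids = hits$id,
       n_directions = if (bidirectional) 2L else 1L)
}

#' Numerical density from disector counts
#'
#' The standard disector estimator \eqn{N_V = \sum Q^- / (n \, a \, h)}:
#' total count divided by the total disector probe volume (number of
#' disectors times frame area times disector height).
#'
#' @param q_minus total Q-minus count over all disectors.
#' @param frame a [disector_frame()] (supplies the frame area).
#' @param n_disectors number of disectors contributing to the count.
#' @param height_nm disector height h in nanometres. For a
#'   reference/lookup pair separated by one intervening section,
#'   disappearance is assessed over the slab between the two section
#'   planes, so h = 2 x section thickness (see
#'   [disector_height_nm()]); passing one section thickness instead is
#'   possible but biases the estimate upward for objects taller than
#'   one section.
#' @return synapses per cubic micrometre.
#' @export
numerical_density <- function(q_minus, frame, n_disectors, height_nm) {
  stopifnot(q_minus >= 0, n_disectors >= 1, height_nm > 0)
  a <- frame$width_um * frame$height_um
  q_minus / (n_disectors * a * (height_nm / 1000))
}

#' Disector height for a stack/frame pair
#'
#' Height of the slab over which disappearance is assessed: the
#' distance between the reference and lookup section planes,
#' \code{(lookup - reference) x section thickness} (= 2 sections for
#' the standard one-intervening-section pair). Objects with z-extent
#' smaller than one section can escape a spaced disector entirely;
#' that residual small-object bias is inherent to the design and is
#' flagged in results metadata.
#'
#' @param stack a [section_stack()].
#' @param frame a [disector_frame()].
#' @return height in nanometres.
#' @export
disector_height_nm <- function(stack, frame) {
  (frame$lookup_index - frame$reference_index) * stack$section_thickness_nm
}

#' Target composition with simultaneous confidence intervals
#'
#' Turns disector target counts into proportions with Goodman (1965)
#' simultaneous 95 percent multinomial confidence intervals.
#'
#' @param counts named non-negative integer vector of counts by target
#'   category; total must be positive.
#' @param conf_level simultaneous confidence level (default 0.95).
#' @return data.frame with \code{category, count, proportion, lower,
#'   upper}.
#' @export
composition_estimate <- function(counts, conf_level = 0.95) {
  counts <- as.numeric(counts)
  k <- length(counts)
  n <- sum(counts)
  if (n <= 0) stop("total count must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  a <- stats::qchisq(1 - (1 - conf_level) / k, df = 1)
  p <- counts / n
  half <- sqrt(a * (a + 4 * counts * (n - counts) / n))
  lower <- (a + 2 * counts - half) / (2 * (n + a))
  upper <- (a + 2 * counts + half) / (2 * (n + a))
  nm <- names(counts)
  if (is.null(nm)) nm <- paste0("cat", seq_len(k))
  data.frame(category = nm, count = counts, proportion = p,
             lower = pmax(0, lower), upper = pmin(1, upper))
}

#' Systematic random sampling sites
#'
#' Regular lattice of sampling positions over a rectangular extent with
#' a single uniform random phase, the standard systematic uniform
#' random sampling scheme of design-based stereology. Deterministic
#' under \code{seed}.
#'
#' @param extent_um length-2 numeric, sampled region size (x, y).
#' @param n_sites number of sites (>= 1).
#' @param seed integer seed for the random phase.
#' @return n_sites x 2 matrix of site offsets in micrometres.
#' @export
systematic_random_sites <- function(extent_um, n_sites, seed = 1L) {
  stopifnot(length(extent_um) == 2L, all(extent_um > 0), n_sites >= 1)
  # lattice shape approximately proportional to the extent
  nx <- max(1L, round(sqrt(n_sites * extent_um[1] / extent_um[2])))
  ny <- ceiling(n_sites / nx)
  sx <- extent_um[1] / nx
  sy <- extent_um[2] / ny
  with_seed(child_seed(seed, "sur_sites"), {
    phase <- stats::runif(2)
    gx <- (seq_len(nx) - 1 + phase[1]) * sx
    gy <- (seq_len(ny) - 1 + phase[2]) * sy
    g <- cbind(x = rep(gx, times = ny), y = rep(gy, each = nx))
    g[seq_len(n_sites), , drop = FALSE]
  })
}
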