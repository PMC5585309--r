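#' Configuration for the synthetic-data generators
#'
#' Bundles the free parameters of the synthetic study conditions: the
#' orientation-map raster, the virtual neuropil, and the class mix of
#' candidate postsynaptic sites. All generators are pure functions of
#' (config, seed): identical configs give bit-identical outputs.
#'
#' @param seed integer root seed; child streams are derived per
#'   generator with [child_seed()].
#' @param map_size_px integer pair, map raster size (rows, cols);
#'   at least 32 x 32.
#' @param pixel_um micrometres per map pixel.
#' @param map_bandpass length-2 numeric, annular band (low, high) in
#'   cycles/mm used to filter the complex noise field; low < high.
#' @param neuropil_density candidate synaptic sites per cubic
#'   micrometre. The study's own disector-derived density is not
#'   published, so this is a free parameter; the default 0.3 is a
#'   typical cortical neuropil synapse density.
#' @param class_fractions named proportions over the four site classes
#'   \code{spine_spiny}, \code{shaft_spiny}, \code{shaft_smooth},
#'   \code{soma}; must sum to 1.
#' @param cube_um edge length of the virtual neuropil cube (default 500).
#' @return an object of class \code{synth_config}.
#' @export
synth_config <- function(seed = 1L,
                         map_size_px = c(128L, 128L),
                         pixel_um = 20,
                         map_bandpass = c(0.5, 1.5),
                         neuropil_density = 0.3,
                         class_fractions = c(spine_spiny = 0.70,
                                             shaft_spiny = 0.05,
                                             shaft_smooth = 0.20,
                                             soma = 0.05),
                         cube_um = 500) {
  stopifnot(length(map_size_px) == 2L, all(map_size_px >= 32L))
  stopifnot(pixel_um > 0, neuropil_density > 0, cube_um > 0)
  if (length(map_bandpass) != 2L || map_bandpass[1] >= map_bandpass[2]) {
    stop("degenerate bandpass: require low < high")
  }
  want <- c("spine_spiny", "shaft_spiny", "shaft_smooth", "soma")
  if (!setequal(names(class_fractions), want)) {
    stop("class_fractions must be named over: ", paste(want, collapse = ", "))
  }
  class_fractions <- class_fractions[want]
  if (abs(sum(class_fractions) - 1) > 1e-9 || any(class_fractions < 0)) {
    stop("class_fractions must be non-negative and sum to 1")
  }
  structure(
    list(seed = as.integer(seed),
         map_size_px = as.integer(map_size_px),
         pixel_um = pixel_um,
         map_bandpass = as.numeric(map_bandpass),
         neuropil_density = neuropil_density,
         class_fractions = class_fractions,
         cube_um = cube_um),
    class = "synth_config")
}

#' Synthesise a pinwheel-rich orientation map
#'
#' Standard construction for model orientation maps: complex Gaussian
#' white noise is annular-bandpass filtered in the Fourier domain (band
#' in cycles/mm set by \code{cfg$map_bandpass}); the preferred
#' orientation at each pixel is half the argument of the filtered
#' complex field and the tuning magnitude is its modulus. Zeros of the
#' field are pinwheel centres. Deterministic under \code{cfg$seed}.
#'
#' @param cfg a [synth_config()].
#' @param field optional complex matrix overriding the filtered-noise
#'   field (used to construct maps with known analytic structure, e.g.
#'   a constant-phase field gives a uniform map).
#' @return an [orientation_map()].
#' @export
make_orientation_map <- function(cfg, field = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  nr <- cfg$map_size_px[1]; nc <- cfg$map_size_px[2]
  if (is.null(field)) {
    z <- with_seed(child_seed(cfg$seed, "orientation_map"), {
      matrix(complex(real = stats::rnorm(nr * nc),
                     imaginary = stats::rnorm(nr * nc)), nr, nc)
    })
    # frequency magnitude in cycles/mm on the FFT grid
    fr <- fft_freq(nr, cfg$pixel_um)   # cycles/mm along rows
    fc <- fft_freq(nc, cfg$pixel_um)
    fmag <- sqrt(outer(fr^2, fc^2, `+`))
    mask <- fmag >= cfg$map_bandpass[1] & fmag <= cfg$map_bandpass[2]
    if (!any(mask)) {
      stop("bandpass annulus contains no Fourier modes for this raster")
    }
    Z <- stats::fft(z) * mask
    field <- stats::fft(Z, inverse = TRUE) / (nr * nc)
  } else {
    stopifnot(is.matrix(field), identical(dim(field), c(nr, nc)))
  }
  ang <- wrap180((Arg(field) %% (2 * pi)) / 2 * 180 / pi)
  mag <- Mod(field)
  if (max(mag) > 0) mag <- mag / max(mag)
  ang[mag == 0] <- NA_real_
  orientation_map(ang, mag, cfg$pixel_um)
}

# FFT sample frequencies in cycles/mm for n samples spaced pixel_um apart.
fft_freq <- function(n, pixel_um) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / (n * pixel_um / 1000)
}

#' Generate a pyramidal-cell morphology placed in chosen map domains
#'
#' Builds an SWC-valid tree (single soma root, acyclic, parents precede
#' children) whose dendritic nodes and local-cluster boutons lie on map
#' pixels preferring approximately \code{local_domain_deg}, and whose
#' distal bouton cluster lies on pixels preferring approximately
#' \code{distal_domain_deg} at lateral offset \code{distal_offset_um}
#' from the soma. Candidate pixels must match the requested orientation
#' within \code{domain_tol_deg}; the tight default tolerance guarantees
#' that downstream similarity indices behave as constructed (same-domain
#' placement SI near 1, orthogonal placement SI near 0).
#'
#' @param cfg a [synth_config()].
#' @param map an [orientation_map()], typically [make_orientation_map()].
#' @param local_domain_deg orientation (degrees) of the domain holding
#'   soma, dendrites and local cluster.
#' @param distal_domain_deg orientation of the distal cluster's domain.
#' @param distal_offset_um requested lateral soma-to-distal-cluster
#'   offset (> 0).
#' @param n_dendrite,n_local,n_distal node counts for dendritic tree and
#'   the two bouton clusters.
#' @param domain_tol_deg half-width of the accepted orientation mismatch
#'   when selecting pixels (degrees).
#' @return a [morphology()].
#' @export
make_morphology <- function(cfg, map, local_domain_deg, distal_domain_deg,
                            distal_offset_um,
                            n_dendrite = 40L, n_local = 25L, n_distal = 25L,
                            domain_tol_deg = 4) {
  stopifnot(inherits(cfg, "synth_config"), inherits(map, "orientation_map"))
  if (distal_offset_um <= 0) stop("distal_offset_um must be > 0")
  d <- dim(map$angle_deg)
  px <- map$pixel_um
  # pixel-centre coordinates in um
  xs <- (seq_len(d[2]) - 0.5) * px
  ys <- (seq_len(d[1]) - 0.5) * px
  coords <- cbind(x = rep(xs, each = d[1]), y = rep(ys, times = d[2]))
  ang <- as.vector(map$angle_deg)
  mag <- as.vector(map$magnitude)

  cand_local <- which(!is.na(ang) &
    acute_orientation_diff(ang, local_domain_deg) <= domain_tol_deg)
  cand_distal <- which(!is.na(ang) &
    acute_orientation_diff(ang, distal_domain_deg) <= domain_tol_deg)
  if (!length(cand_local)) {
    stop(sprintf("no map pixel within %.3g deg of local domain %.3g deg",
                 domain_tol_deg, local_domain_deg))
  }
  if (!length(cand_distal)) {
    stop(sprintf("no map pixel within %.3g deg of distal domain %.3g deg",
                 domain_tol_deg, distal_domain_deg))
  }

  # soma: strongest-magnitude local-domain pixel not too close to the edge
  soma_i <- cand_local[order(-mag[cand_local], cand_local)][1]
  soma <- coords[soma_i, ]

  # distal centre: local-domain-matched pixel nearest the requested offset
  dd <- sqrt((coords[cand_distal, 1] - soma[1])^2 +
             (coords[cand_distal, 2] - soma[2])^2)
  distal_i <- cand_distal[order(abs(dd - distal_offset_um), cand_distal)][1]
  distal <- coords[distal_i, ]

  near_k <- function(cand, centre, k) {
    dc <- sqrt((coords[cand, 1] - centre[1])^2 +
               (coords[cand, 2] - centre[2])^2)
    cand[order(dc, cand)][seq_len(min(k, length(cand)))]
  }
  dend_i <- near_k(cand_local, soma, n_dendrite)
  loc_i <- near_k(cand_local, soma, n_local)
  dist_i <- near_k(cand_distal, distal, n_distal)

  # deterministic sub-pixel jitter so nodes are not exactly coincident
  jit <- with_seed(child_seed(cfg$seed, "morphology_jitter"), {
    n <- length(dend_i) + length(loc_i) + length(dist_i)
    matrix(stats::runif(2 * n, -0.25, 0.25) * px, ncol = 2)
  })

  nodes <- list()
  nodes[[1]] <- data.frame(id = 1L, type = 1L, x = soma[1], y = soma[2],
                           z = 0, radius = 8, parent = -1L)
  nid <- 1L
  j <- 0L
  add_nodes <- function(nodes, idx, type, parent, radius, z) {
    for (i in idx) {
      j <<- j + 1L; nid <<- nid + 1L
      nodes[[length(nodes) + 1L]] <- data.frame(
        id = nid, type = type,
        x = coords[i, 1] + jit[j, 1], y = coords[i, 2] + jit[j, 2],
        z = z, radius = radius, parent = parent)
    }
    nodes
  }
  # dendrites: star from soma
  nodes <- add_nodes(nodes, dend_i, 3L, 1L, 0.5, 0)
  # axon: straight path soma -> distal centre, ~20 um spacing
  nsteps <- max(2L, ceiling(sqrt(sum((distal - soma)^2)) / 20))
  first_axon <- nid + 1L
  for (s in seq_len(nsteps)) {
    nid <- nid + 1L
    f <- s / nsteps
    nodes[[length(nodes) + 1L]] <- data.frame(
      id = nid, type = 2L,
      x = soma[1] + f * (distal[1] - soma[1]),
      y = soma[2] + f * (distal[2] - soma[2]),
      z = 0, radius = 0.2,
      parent = if (s == 1L) 1L else nid - 1L)
  }
  last_axon <- nid
  # bouton clusters: local boutons hang off the first axon node,
  # distal boutons off the last
  nodes <- add_nodes(nodes, loc_i, 7L, first_axon, 0.3, 0)
  nodes <- add_nodes(nodes, dist_i, 8L, last_axon, 0.3, 0)
  morphology(do.call(rbind, nodes))
}

#' Neuron morphology with bouton markers
#'
#' SWC-style node table (\code{id, type, x, y, z, radius, parent}) with
#' the bouton clusters encoded as custom node types: 7 = local-cluster
#' bouton, 8 = distal-cluster bouton. Validates the SWC contract: ids
#' unique, single root, every parent precedes its child (acyclic).
#'
#' @param nodes data.frame with the seven SWC columns.
#' @return object of class \code{morphology}.
#' @export
morphology <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) {
    stop("nodes must have columns: ", paste(need, collapse = ", "))
  }
  nodes <- nodes[, need]
  rownames(nodes) <- NULL
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  roots <- which(nodes$parent == -1L)
  if (length(roots) != 1L) stop("exactly one root (parent -1) required")
  seen <- logical(max(nodes$id))
  for (r in seq_len(nrow(nodes))) {
    p <- nodes$parent[r]
    if (p != -1L && (p > length(seen) || !seen[p])) {
      stop("parent must precede child in SWC order (node ",
           nodes$id[r], ")")
    }
    seen[nodes$id[r]] <- TRUE
  }
  structure(list(nodes = nodes), class = "morphology")
}

#' Extract point samples from a morphology
#'
#' Returns the 2D (x, y) positions of the dendritic nodes or of one
#' bouton cluster, as a point sample for the similarity-index
#' computation.
#'
#' @param morph a [morphology()].
#' @param what one of \code{"dendrites"}, \code{"local"}, \code{"distal"}.
#' @return a [point_sample()].
#' @export
morphology_sample <- function(morph, what = c("dendrites", "local", "distal")) {
  what <- match.arg(what)
  stopifnot(inherits(morph, "morphology"))
  type <- switch(what, dendrites = 3L, local = 7L, distal = 8L)
  sel <- morph$nodes[morph$nodes$type == type, c("x", "y")]
  point_sample(as.matrix(sel),
               label = if (what == "dendrites") "dendrites" else "cluster",
               cluster_kind = switch(what, dendrites = "none", what))
}

#' Poisson field of candidate postsynaptic sites
#'
#' Homogeneous Poisson point process in the virtual neuropil cube: the
#' site count is Poisson with mean density x volume, positions are
#' i.i.d. uniform in the cube, and class labels are i.i.d. from
#' \code{cfg$class_fractions}.
#'
#' @param cfg a [synth_config()].
#' @return object of class \code{neuropil_field}: data.frame
#'   \code{x, y, z, class} with attributes \code{cube_um} and
#'   \code{density}.
#' @export
make_neuropil_field <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  vol <- cfg$cube_um^3
  if (cfg$neuropil_density * vol >= 1e9) {
    stop("refusing to generate >= 1e9 sites; lower density or cube size")
  }
  with_seed(child_seed(cfg$seed, "neuropil_field"), {
    n <- stats::rpois(1, cfg$neuropil_density * vol)
    df <- data.frame(
      x = stats::runif(n, 0, cfg$cube_um),
      y = stats::runif(n, 0, cfg$cube_um),
      z = stats::runif(n, 0, cfg$cube_um),
      class = sample(names(cfg$class_fractions), n, replace = TRUE,
                     prob = cfg$class_fractions))
    structure(df, cube_um = cfg$cube_um, density = cfg$neuropil_density,
              class = c("neuropil_field", class(df)))
  })
}

#' Serial-section contour stack
#'
#' Ordered list of polygon/polyline contours with the section thickness:
#' \code{psd_trace} contours are open polylines (the linear profile of a
#' postsynaptic density in one section), \code{cross_section} contours
#' are closed polygons (one cut through a spine or dendrite).
#'
#' @param contours list of lists with elements \code{section} (integer),
#'   \code{vertices} (n x 2 numeric matrix, micrometres) and \code{kind}
#'   (\code{"psd_trace"} or \code{"cross_section"}).
#' @param section_nm section thickness in nanometres.
#' @return object of class \code{contour_stack}.
#' @export
contour_stack <- function(contours, section_nm) {
  stopifnot(section_nm > 0)
  for (ct in contours) {
    stopifnot(is.numeric(ct$section),
              is.matrix(ct$vertices), ncol(ct$vertices) == 2L,
              ct$kind %in% c("psd_trace", "cross_section"))
  }
  ord <- order(vapply(contours, `[[`, numeric(1), "section"))
  structure(list(contours = contours[ord], section_nm = section_nm),
            class = "contour_stack")
}

#' Synthetic contour stacks of known analytic measure
#'
#' Builds serial-section fixtures whose true measure is known exactly:
#' \describe{
#'   \item{disc}{a flat PSD disc of area \code{target_area_um2} standing
#'     perpendicular to the section plane, represented by one straight
#'     trace per section whose length is the exact area of the disc band
#'     in that section divided by the thickness, so the summed
#'     trace-length x thickness estimator recovers the target area.}
#'   \item{prism}{a square prism of volume \code{target_volume_um3};
#'     Cavalieri is exact for prisms.}
#'   \item{spine}{a sphere of volume \code{target_volume_um3}, sections
#'     carrying 64-gon cross-sections; Cavalieri recovers the volume to
#'     within the stated discretisation error.}
#' }
#'
#' @param shape \code{"disc"}, \code{"prism"} or \code{"spine"}.
#' @param target_area_um2 target PSD area (disc only), micrometres^2.
#' @param target_volume_um3 target volume (prism/spine), micrometres^3.
#' @param section_nm section thickness in nanometres (default 60).
#' @return a [contour_stack()].
#' @export
make_contour_stack <- function(shape = c("disc", "prism", "spine"),
                               target_area_um2 = NULL,
                               target_volume_um3 = NULL,
                               section_nm = 60) {
  shape <- match.arg(shape)
  t_um <- section_nm / 1000
  stopifnot(section_nm > 0)
  if (shape == "disc") {
    if (is.null(target_area_um2) || target_area_um2 <= 0) {
      stop("disc requires target_area_um2 > 0")
    }
    r <- sqrt(target_area_um2 / pi)
    nsec <- ceiling(2 * r / t_um)
    contours <- list()
    for (k in seq_len(nsec)) {
      z0 <- -r + (k - 1) * t_um
      z1 <- min(z0 + t_um, r)
      # exact area of the disc band between z0 and z1
      bandA <- disc_band_area(r, z0, z1)
      if (bandA <= 0) next
      half <- bandA / t_um / 2
      contours[[length(contours) + 1L]] <- list(
        section = k, kind = "psd_trace",
        vertices = cbind(c(-half, half), c(0, 0)))
    }
    return(contour_stack(contours, section_nm))
  }
  if (is.null(target_volume_um3) || target_volume_um3 <= 0) {
    stop(shape, " requires target_volume_um3 > 0")
  }
  if (shape == "prism") {
    nsec <- 10L
    a <- target_volume_um3 / (nsec * t_um)  # per-section polygon area
    s <- sqrt(a)
    sq <- cbind(c(0, s, s, 0), c(0, 0, s, s))
    contours <- lapply(seq_len(nsec), function(k) {
      list(section = k, kind = "cross_section", vertices = sq)
    })
    return(contour_stack(contours, section_nm))
  }
  # sphere ("spine")
  r <- (3 * target_volume_um3 / (4 * pi))^(1 / 3)
  nsec <- ceiling(2 * r / t_um)
  th <- seq(0, 2 * pi, length.out = 65L)[-65L]
  contours <- list()
  for (k in seq_len(nsec)) {
    zc <- -r + (k - 0.5) * t_um
    if (zc <= -r || zc >= r) next
    rho <- sqrt(r^2 - zc^2)
    # inflate the 64-gon so its area equals the circle cross-section
    rho <- rho / sqrt(sin(2 * pi / 64) / (2 * pi / 64))
    contours[[length(contours) + 1L]] <- list(
      section = k, kind = "cross_section",
      vertices = cbind(rho * cos(th), rho * sin(th)))
  }
  contour_stack(contours, section_nm)
}

# exact area of a disc (radius r, centred at 0) between chords z0 < z1
disc_band_area <- function(r, z0, z1) {
  z0 <- max(z0, -r); z1 <- min(z1, r)
  if (z1 <= z0) return(0)
  f <- function(z) z * sqrt(pmax(r^2 - z^2, 0)) + r^2 * asin(pmin(pmax(z / r, -1), 1))
  f(z1) - f(z0)
}
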