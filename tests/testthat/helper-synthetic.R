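# Shared in-code fixtures for the test suite.

# orientation map with constant angle everywhere
const_map <- function(angle_deg, nr = 8, nc = 8, pixel_um = 1, mag = 1) {
  orientation_map(matrix(angle_deg, nr, nc), matrix(mag, nr, nc), pixel_um)
}

# 1 x n map holding the given angles (unit magnitude unless given)
row_map <- function(angles, mags = rep(1, length(angles)), pixel_um = 1) {
  orientation_map(matrix(angles, 1), matrix(mags, 1), pixel_um)
}

# positions of the pixel centres of a 1 x n map
row_centres <- function(n, pixel_um = 1) {
  cbind((seq_len(n) - 0.5) * pixel_um, 0.5 * pixel_um)
}

# condition stack with uniform response grids, one value per condition
uniform_stack <- function(angles, values, nr = 4, nc = 4) {
  condition_stack(angles, lapply(values, function(v) matrix(v, nr, nc)))
}

# closed polygon approximating a circle, inflated so its area is exact
circle_poly <- function(r, n = 128L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r_eff <- r / sqrt(sin(2 * pi / n) / (2 * pi / n))
  cbind(r_eff * cos(th), r_eff * sin(th))
}

# serial-section synapse stack with heterogeneous z-extents (in units of
# sections, continuous >= 1) whose true numerical density is known:
# synapse tops are uniform over (0, n_sections - 1], which the
# one-intervening-section disector probes tile exactly
height_stack <- function(n_synapses, n_sections = 60, extent_um = 40,
                         thickness_nm = 50, height_range = c(1, 5),
                         seed = 1) {
  set.seed(seed)
  tops <- stats::runif(n_synapses, 0, n_sections - 1)
  hts <- stats::runif(n_synapses, height_range[1], height_range[2])
  x <- stats::runif(n_synapses, 0, extent_um)
  y <- stats::runif(n_synapses, 0, extent_um)
  rows <- vector("list", n_synapses)
  for (i in seq_len(n_synapses)) {
    lo <- max(1L, floor(tops[i] - hts[i]) + 1L)
    hi <- min(n_sections, ceiling(tops[i]))
    if (hi < 1L) next
    rows[[i]] <- data.frame(section = lo:hi, id = i, x = x[i], y = y[i],
                            type = "asymmetric", target = "spine",
                            class = "spiny")
  }
  stk <- section_stack(do.call(rbind, rows),
                       section_thickness_nm = thickness_nm,
                       n_sections = n_sections)
  attr(stk, "true_density") <-
    n_synapses / (extent_um^2 * (n_sections - 1) * thickness_nm / 1000)
  attr(stk, "extent_um") <- extent_um
  stk
}

# sum of Q-minus over n random systematic disector frames; returns the
# density estimate using the reference-to-lookup slab height
estimate_density <- function(stk, n_disectors, frame_um = 5, seed = 1) {
  set.seed(seed)
  W <- attr(stk, "extent_um")
  q <- 0
  fr0 <- disector_frame(frame_um, frame_um, c(0, 0), 1)
  for (j in seq_len(n_disectors)) {
    fr <- disector_frame(frame_um, frame_um,
                         c(stats::runif(1, 0, W - frame_um),
                           stats::runif(1, 0, W - frame_um)),
                         sample.int(stk$n_sections - 2L, 1L))
    q <- q + disector_count(stk, fr)$q_minus
  }
  numerical_density(q, fr0, n_disectors, disector_height_nm(stk, fr0))
}

# small neuropil field for walk tests (returns field + its config)
walk_test_field <- function(seed = 3, cube_um = 40, density = 0.3,
                            fractions = c(spine_spiny = 0.70,
                                          shaft_spiny = 0.05,
                                          shaft_smooth = 0.20,
                                          soma = 0.05)) {
  cfg <- synth_config(seed = seed, cube_um = cube_um,
                      neuropil_density = density,
                      class_fractions = fractions)
  make_neuropil_field(cfg)
}
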