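test_that("PSD area sums trace length times thickness", {
  # single 1 um trace at 60 nm: 0.06 um^2
  stk <- contour_stack(list(list(section = 1, kind = "psd_trace",
                                 vertices = cbind(c(0, 1), c(0, 0)))), 60)
  expect_equal(psd_area(stk), 0.06)
  expect_error(psd_area(contour_stack(list(), 60)), "no psd_trace")
  # synthetic disc fixture at the printed quadruplet size
  expect_equal(psd_area(make_contour_stack("disc", target_area_um2 = 0.18)),
               0.18, tolerance = 0.02)
})

test_that("PSD area matches the closed-form sphere-band oracle", {
  # equatorial band of a sphere: area 2*pi*R*h; traces are circles of
  # radius rho(z) at each section through the band
  R <- 0.5; h <- 0.3; t_nm <- 60; t_um <- t_nm / 1000
  nsec <- round(h / t_um)
  contours <- lapply(seq_len(nsec), function(k) {
    z <- -h / 2 + (k - 0.5) * t_um
    rho <- sqrt(R^2 - z^2)
    th <- seq(0, 2 * pi, length.out = 257)
    list(section = k, kind = "psd_trace",
         vertices = cbind(rho * cos(th), rho * sin(th)))
  })
  est <- psd_area(contour_stack(contours, t_nm))
  expect_equal(est, 2 * pi * R * h, tolerance = 0.03)
})

test_that("Cavalieri volume is exact for prisms and accurate for spheres", {
  expect_equal(spine_volume(make_contour_stack("prism",
                                               target_volume_um3 = 0.1)),
               0.1, tolerance = 1e-9)
  expect_error(spine_volume(contour_stack(list(), 60)), "no cross_section")
  r <- 0.3
  v_true <- 4 / 3 * pi * r^3
  sph <- make_contour_stack("spine", target_volume_um3 = v_true)
  expect_equal(spine_volume(sph), v_true, tolerance = 0.03)
})

test_that("dendrite radius is the mean equivalent-circle radius", {
  circ <- function(r, k) list(section = k, kind = "cross_section",
                              vertices = circle_poly(r))
  stk <- contour_stack(list(circ(0.5, 1), circ(0.5, 2), circ(0.5, 3)), 60)
  expect_equal(dendrite_radius(stk), 0.5, tolerance = 1e-6)
  # ellipse with semi-axes 0.4 and 0.1: equivalent radius sqrt(ab) = 0.2
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  ell <- cbind(0.4 * cos(th), 0.1 * sin(th))
  stk2 <- contour_stack(lapply(1:3, function(k)
    list(section = k, kind = "cross_section", vertices = ell)), 60)
  expect_equal(dendrite_radius(stk2), 0.2, tolerance = 1e-3)
  expect_error(dendrite_radius(contour_stack(list(circ(0.5, 1),
                                                  circ(0.5, 2)), 60)),
               "at least 3")
})

test_that("measures are additive, rotation-invariant, and scale correctly", {
  full <- make_contour_stack("spine", target_volume_um3 = 0.2)
  ns <- length(full$contours)
  lower <- contour_stack(full$contours[1:floor(ns / 2)], full$section_nm)
  upper <- contour_stack(full$contours[(floor(ns / 2) + 1):ns],
                         full$section_nm)
  expect_equal(spine_volume(lower) + spine_volume(upper),
               spine_volume(full), tolerance = 1e-12)
  # rigid in-plane rotation leaves both measures unchanged
  ang <- 0.63
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  rot <- contour_stack(lapply(full$contours, function(ct) {
    ct$vertices <- ct$vertices %*% Rm
    ct
  }), full$section_nm)
  expect_equal(spine_volume(rot), spine_volume(full), tolerance = 1e-9)
  disc <- make_contour_stack("disc", target_area_um2 = 0.15)
  disc_rot <- contour_stack(lapply(disc$contours, function(ct) {
    ct$vertices <- ct$vertices %*% Rm
    ct
  }), disc$section_nm)
  expect_equal(psd_area(disc_rot), psd_area(disc), tolerance = 1e-9)
  # isotropic rescaling: areas scale as s^2, volumes as s^3
  s <- 1.7
  expect_equal(psd_area(scale_contour_stack(disc, s)),
               s^2 * psd_area(disc), tolerance = 1e-9)
  expect_equal(spine_volume(scale_contour_stack(full, s)),
               s^3 * spine_volume(full), tolerance = 1e-9)
})

test_that("shrinkage correction commutes with measurement", {
  f <- 0.11
  disc <- make_contour_stack("disc", target_area_um2 = 0.12)
  sph <- make_contour_stack("spine", target_volume_um3 = 0.08)
  expect_equal(psd_area(scale_contour_stack(disc, 1 / (1 - f))),
               shrinkage_correct(psd_area(disc), f, power = 2L),
               tolerance = 1e-9)
  expect_equal(spine_volume(scale_contour_stack(sph, 1 / (1 - f))),
               shrinkage_correct(spine_volume(sph), f, power = 3L),
               tolerance = 1e-9)
})

test_that("dendrite classification follows the spiny/smooth criteria", {
  expect_equal(classify_dendrite(10, 15, 0)$class, "spiny")
  # spine-free shaft densely covered with asymmetric synapses: smooth
  expect_equal(classify_dendrite(10, 0, 12)$class, "smooth")
  expect_equal(classify_dendrite(10, 0, 1)$class, "unclassified")
  short <- classify_dendrite(1.5, 3, 0)
  expect_equal(short$class, "unclassified")
  expect_match(short$reason, "shorter")
})
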