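test_that("synth_config validates its invariants", {
  expect_error(synth_config(map_bandpass = c(2, 1)), "degenerate bandpass")
  expect_error(synth_config(class_fractions = c(spine_spiny = 0.5,
                                                shaft_spiny = 0.1,
                                                shaft_smooth = 0.2,
                                                soma = 0.1)),
               "sum to 1")
  expect_error(synth_config(map_size_px = c(16, 16)))
})

test_that("synthetic orientation maps are deterministic and in range", {
  cfg <- synth_config(seed = 21, map_size_px = c(64, 64), pixel_um = 20,
                      map_bandpass = c(0.5, 2))
  m1 <- make_orientation_map(cfg)
  m2 <- make_orientation_map(cfg)
  expect_identical(m1$angle_deg, m2$angle_deg)
  expect_identical(m1$magnitude, m2$magnitude)
  ok <- !is.na(m1$angle_deg)
  expect_true(all(m1$angle_deg[ok] >= 0 & m1$angle_deg[ok] < 180))
  expect_true(all(m1$magnitude >= 0 & m1$magnitude <= 1))
})

test_that("a constant-phase complex field gives angle = arg/2 everywhere", {
  cfg <- synth_config(seed = 1, map_size_px = c(32, 32))
  f <- matrix(complex(modulus = 1, argument = pi / 2), 32, 32)
  m <- make_orientation_map(cfg, field = f)
  expect_true(all(abs(m$angle_deg - 45) < 1e-9))
})

test_that("filtered-noise map angles are isotropic across seeds", {
  # decimated samples from independent maps; Rayleigh test on doubled angles
  angs <- unlist(lapply(1:8, function(s) {
    cfg <- synth_config(seed = 100 + s, map_size_px = c(256, 256),
                        pixel_um = 20, map_bandpass = c(1, 3))
    m <- make_orientation_map(cfg)
    m$angle_deg[seq(32, 256, by = 64), seq(32, 256, by = 64)]
  }))
  angs <- angs[!is.na(angs)]
  th <- 2 * angs * pi / 180
  n <- length(th)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))  # Rayleigh approximation
  expect_gt(p, 0.01)
})

test_that("morphologies are SWC-valid, placed in the requested domains, and round-trip", {
  cfg <- synth_config(seed = 7, map_size_px = c(128, 128), pixel_um = 20,
                      map_bandpass = c(0.3, 0.9))
  m <- make_orientation_map(cfg)
  mo <- make_morphology(cfg, m, local_domain_deg = 20,
                        distal_domain_deg = 110, distal_offset_um = 800)
  nd <- mo$nodes
  expect_equal(sum(nd$parent == -1L), 1L)
  expect_true(all(nd$type %in% c(1L, 2L, 3L, 7L, 8L)))
  # parent precedes child
  pos_of <- match(nd$parent, nd$id)
  expect_true(all(is.na(pos_of) | pos_of < seq_len(nrow(nd))))
  # sampled domains match the requests within the selection tolerance
  dend <- morphology_sample(mo, "dendrites")
  expect_lt(acute_orientation_diff(domain_angle(m, dend), 20), 5)
  dist <- morphology_sample(mo, "distal")
  expect_lt(acute_orientation_diff(domain_angle(m, dist), 110), 5)
  # distal cluster sits near the requested lateral offset
  soma <- nd[nd$type == 1L, c("x", "y")]
  cen <- colMeans(nd[nd$type == 8L, c("x", "y")])
  off <- sqrt(sum((cen - unlist(soma))^2))
  expect_gt(off, 0.5 * 800)
  expect_lt(off, 1.5 * 800)
  # SWC round-trip
  f <- tempfile(fileext = ".swc")
  on.exit(unlink(f))
  write_swc(mo, f)
  expect_equal(read_swc(f)$nodes, mo$nodes)
})

test_that("morphology generation fails when a requested domain is absent", {
  cfg <- synth_config(seed = 1, map_size_px = c(32, 32))
  m45 <- make_orientation_map(cfg,
                              field = matrix(complex(modulus = 1,
                                                     argument = pi / 2),
                                             32, 32))
  expect_error(make_morphology(cfg, m45, local_domain_deg = 45,
                               distal_domain_deg = 135,
                               distal_offset_um = 100),
               "no map pixel within")
})

test_that("neuropil fields follow Poisson counts and i.i.d. class labels", {
  for (s in 1:4) {
    cfg <- synth_config(seed = s, cube_um = 100, neuropil_density = 0.001)
    fld <- make_neuropil_field(cfg)
    expect_lt(abs(nrow(fld) - 1000), 3 * sqrt(1000))
    expect_true(all(fld$x >= 0 & fld$x <= 100))
  }
  # degenerate fractions: every label is spine_spiny
  cfg1 <- synth_config(seed = 2, cube_um = 50, neuropil_density = 0.01,
                       class_fractions = c(spine_spiny = 1, shaft_spiny = 0,
                                           shaft_smooth = 0, soma = 0))
  expect_true(all(make_neuropil_field(cfg1)$class == "spine_spiny"))
  # empirical proportions at n ~ 1e5 within binomial 99% CI
  fr <- c(spine_spiny = 0.7, shaft_spiny = 0.05, shaft_smooth = 0.2,
          soma = 0.05)
  cfg2 <- synth_config(seed = 3, cube_um = 100, neuropil_density = 0.1,
                       class_fractions = fr)
  fld2 <- make_neuropil_field(cfg2)
  n <- nrow(fld2)
  for (cl in names(fr)) {
    phat <- mean(fld2$class == cl)
    half <- stats::qnorm(0.995) * sqrt(fr[[cl]] * (1 - fr[[cl]]) / n)
    expect_lt(abs(phat - fr[[cl]]), half + 1e-12)
  }
  # determinism
  expect_identical(make_neuropil_field(cfg2), fld2)
})

test_that("contour-stack generators hit their analytic targets", {
  # prism: Cavalieri is exact
  pr <- make_contour_stack("prism", target_volume_um3 = 1.0)
  expect_equal(spine_volume(pr), 1.0, tolerance = 1e-9)
  # disc PSD at the quadruplet fixture size
  dc <- make_contour_stack("disc", target_area_um2 = 0.18)
  expect_equal(psd_area(dc), 0.18, tolerance = 0.02)
  # sphere volume within the stated discretisation error
  sp <- make_contour_stack("spine", target_volume_um3 = 0.1)
  expect_equal(spine_volume(sp), 0.1, tolerance = 0.02)
  expect_error(make_contour_stack("disc", target_area_um2 = 0),
               "target_area_um2 > 0")
})
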