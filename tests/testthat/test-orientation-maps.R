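test_that("cocktail-blank normalisation divides by the summed response", {
  angles <- seq(0, 157.5, by = 22.5)
  # identical uniform responses: every pixel of every single map is 1/8
  st <- uniform_stack(angles, rep(3, 8))
  expect_equal(cocktail_blank_map(st, 45),
               matrix(1 / 8, 4, 4))
  # one condition responds 2, the others 1: map value 2/9 at every pixel
  st2 <- uniform_stack(angles, c(1, 1, 2, 1, 1, 1, 1, 1))
  expect_equal(cocktail_blank_map(st2, 45), matrix(2 / 9, 4, 4))
  expect_error(cocktail_blank_map(st2, 10), "not present")
})

test_that("differential maps divide by the orthogonal condition and flag zeros", {
  angles <- seq(0, 157.5, by = 22.5)
  st <- uniform_stack(angles, c(2, 1, 1, 1, 4, 1, 1, 1))
  expect_equal(cocktail_blank_map(st, 0, divisor = "orthogonal"),
               matrix(2 / 4, 4, 4))
  st0 <- uniform_stack(angles, c(2, 1, 1, 1, 0, 1, 1, 1))
  expect_error(cocktail_blank_map(st0, 0, divisor = "orthogonal"),
               "zero denominator")
  err <- tryCatch(cocktail_blank_map(st0, 0, divisor = "orthogonal"),
                  error = conditionMessage)
  expect_match(err, "row 1, col 1")
})

test_that("preference map recovers cosine-tuned orientations within 0.5 degrees", {
  angles <- seq(0, 157.5, by = 22.5)
  for (theta0 in seq(0, 179, by = 7)) {
    resp <- lapply(angles, function(a) {
      matrix(1 + cos(2 * (a - theta0) * pi / 180), 2, 2)
    })
    m <- preference_map(condition_stack(angles, resp))
    err <- min(abs(m$angle_deg[1, 1] - theta0),
               180 - abs(m$angle_deg[1, 1] - theta0))
    expect_lt(err, 0.5)
  }
})

test_that("preference map handles degenerate pixels and single conditions", {
  angles <- seq(0, 157.5, by = 22.5)
  # single nonzero condition: angle equals that stimulus angle everywhere
  resp <- lapply(angles, function(a) matrix(as.numeric(a == 45), 3, 3))
  m <- preference_map(condition_stack(angles, resp))
  expect_true(all(abs(m$angle_deg - 45) < 1e-9))
  # equal responses to all conditions: zero magnitude, undefined angle
  m0 <- preference_map(uniform_stack(angles, rep(1, 8)))
  expect_true(all(m0$magnitude == 0))
  expect_true(all(is.na(m0$angle_deg)))
  expect_error(preference_map(uniform_stack(45, 1)), "two distinct")
})

test_that("preference map is invariant to gain and additive offsets as expected", {
  angles <- seq(0, 157.5, by = 22.5)
  set.seed(11)
  resp <- lapply(angles, function(a) {
    matrix(1.2 + cos(2 * (a - 30) * pi / 180) + stats::runif(4, 0, 0.1), 2, 2)
  })
  base <- preference_map(condition_stack(angles, resp))
  # positive rescaling: identical map (ratio normalisation)
  sc <- preference_map(condition_stack(angles, lapply(resp, function(r) 3.7 * r)))
  expect_equal(sc$angle_deg, base$angle_deg)
  expect_equal(sc$magnitude, base$magnitude)
  # common additive image: same angles, different magnitude
  off <- preference_map(condition_stack(angles, lapply(resp, function(r) r + 2)))
  expect_equal(off$angle_deg, base$angle_deg, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(off$magnitude, base$magnitude)))
})

test_that("rotating all stimulus labels rotates the recovered angles", {
  angles <- seq(0, 157.5, by = 22.5)
  resp <- lapply(angles, function(a) {
    matrix(1 + cos(2 * (a - 50) * pi / 180), 2, 2)
  })
  base <- preference_map(condition_stack(angles, resp))
  for (delta in c(10, 45, 120)) {
    rot <- preference_map(condition_stack(angles + delta, resp))
    d <- (rot$angle_deg - base$angle_deg - delta) %% 180
    expect_true(all(pmin(d, 180 - d) < 1e-6))
  }
})

test_that("sample_map does nearest-pixel lookup and validates extent", {
  m <- row_map(c(10, 50, 90, 130), pixel_um = 2)
  got <- sample_map(m, rbind(c(1, 1), c(5.9, 0.2)))
  expect_equal(got$angle_deg, c(10, 90))
  # zero points: empty result
  expect_equal(nrow(sample_map(m, matrix(numeric(0), 0, 2))), 0L)
  # constant map: constant output at any points
  cm <- const_map(77, pixel_um = 1)
  pts <- cbind(runif(5, 0, 8), runif(5, 0, 8))
  expect_equal(sample_map(cm, pts)$angle_deg, rep(77, 5))
  expect_error(sample_map(m, rbind(c(9, 1))), "outside map extent")
})

test_that("orientation maps round-trip through TIFF plus sidecar", {
  cfg <- synth_config(seed = 5, map_size_px = c(32, 32), pixel_um = 50,
                      map_bandpass = c(0.5, 3))
  m <- make_orientation_map(cfg)
  m$angle_deg[1, 1] <- NA_real_
  m$magnitude[1, 1] <- 0
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_orientation_map(m, path)
  m2 <- read_orientation_map(path)
  expect_equal(m2$pixel_um, m$pixel_um)
  expect_identical(is.na(m2$angle_deg), is.na(m$angle_deg))
  expect_lt(max(abs(m2$angle_deg - m$angle_deg), na.rm = TRUE), 1e-4)
  expect_lt(max(abs(m2$magnitude - m$magnitude)), 1e-6)
})
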