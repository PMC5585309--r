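make_profiles <- function(...) {
  df <- data.frame(...)
  defaults <- list(type = "asymmetric", target = "spine", class = "spiny")
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df
}

test_that("disector counting applies the disappearance rule and frame edges", {
  # synapse A present in both sections, B only in reference
  prof <- make_profiles(section = c(1, 3, 1), id = c("A", "A", "B"),
                        x = c(2, 2, 3), y = c(2, 2, 3))
  stk <- section_stack(prof, n_sections = 3)
  fr <- disector_frame(5, 5, c(0, 0), 1)
  got <- disector_count(stk, fr)
  expect_equal(got$q_minus, 1L)
  expect_equal(got$ids, "B")
  # unbiased frame rule: exclusion (bottom/left) edges excluded,
  # inclusion (top/right) edges included
  prof2 <- make_profiles(section = c(1, 1), id = c("L", "R"),
                         x = c(0, 5), y = c(2, 5))
  stk2 <- section_stack(prof2, n_sections = 3)
  got2 <- disector_count(stk2, fr)
  expect_equal(sort(got2$ids), "R")
  # frame outside the section range errors
  expect_error(disector_count(stk, disector_frame(5, 5, c(0, 0), 2)),
               "outside the stack")
  expect_error(disector_frame(5, 5, c(0, 0), 1, lookup_index = 2),
               "intervening")
})

test_that("disector counts agree with brute-force enumeration", {
  set.seed(31)
  n <- 400
  prof <- do.call(rbind, lapply(seq_len(n), function(i) {
    s0 <- sample(1:10, 1)
    make_profiles(section = s0:min(10, s0 + sample(0:3, 1)), id = i,
                  x = runif(1, 0, 20), y = runif(1, 0, 20))
  }))
  stk <- section_stack(prof, n_sections = 10)
  for (ref in c(1, 4, 8)) {
    fr <- disector_frame(8, 6, c(3, 5), ref)
    got <- disector_count(stk, fr, bidirectional = TRUE)
    # oracle: direct set difference over profile rows, both directions
    brute <- function(r, l) {
      pr <- prof[prof$section == r, ]
      pr <- pr[pr$x > 3 & pr$x <= 11 & pr$y > 5 & pr$y <= 11, ]
      sum(!(pr$id %in% prof$id[prof$section == l]))
    }
    expect_equal(got$q_minus, brute(ref, ref + 2) + brute(ref + 2, ref))
  }
})

test_that("numerical density is the count over the probe volume", {
  fr <- disector_frame(5, 5, c(0, 0), 1)
  expect_equal(numerical_density(5, fr, 10, height_nm = 50), 0.4)
  expect_equal(numerical_density(0, fr, 10, height_nm = 50), 0)
  expect_equal(numerical_density(5, fr, 20, height_nm = 50), 0.2)
})

test_that("the disector estimator is size-unbiased on heterogeneous heights", {
  stk <- height_stack(6000, seed = 42)
  est <- estimate_density(stk, 500, seed = 7)
  truth <- attr(stk, "true_density")
  expect_lt(abs(est - truth) / truth, 0.05)
})

test_that("bidirectional counting doubles the expected count", {
  stk <- height_stack(4000, seed = 8)
  set.seed(12)
  W <- attr(stk, "extent_um")
  q1 <- 0; q2 <- 0
  for (j in 1:400) {
    fr <- disector_frame(5, 5, c(runif(1, 0, W - 5), runif(1, 0, W - 5)),
                         sample.int(stk$n_sections - 2L, 1L))
    q1 <- q1 + disector_count(stk, fr)$q_minus
    q2 <- q2 + disector_count(stk, fr, bidirectional = TRUE)$q_minus
  }
  expect_equal(q2 / q1, 2, tolerance = 0.1)
})

test_that("composition estimates carry calibrated simultaneous CIs", {
  expect_equal(composition_estimate(c(spine = 10, shaft = 0, soma = 0))$proportion,
               c(1, 0, 0))
  expect_error(composition_estimate(c(0, 0)), "> 0")
  # coverage: known fractions, many frames, >= 94/100 runs contain truth
  truth <- c(0.70, 0.25, 0.05)
  set.seed(123)
  hit <- replicate(100, {
    counts <- as.vector(stats::rmultinom(1, 200, truth))
    ci <- composition_estimate(counts)
    all(truth >= ci$lower & truth <= ci$upper)
  })
  expect_gte(sum(hit), 94)
})

test_that("systematic random sites form a uniformly-phased lattice", {
  s1 <- systematic_random_sites(c(10, 10), 1, seed = 3)
  expect_equal(dim(s1), c(1L, 2L))
  expect_true(all(s1 >= 0 & s1 <= 10))
  # lattice spacing equals extent divided by the per-axis grid size
  s9 <- systematic_random_sites(c(12, 12), 9, seed = 5)
  xs <- sort(unique(round(s9[, 1], 9)))
  expect_equal(diff(xs), rep(4, 2), tolerance = 1e-9)
  expect_identical(s9, systematic_random_sites(c(12, 12), 9, seed = 5))
  # phase uniformity: quadrant occupancy of single sites across seeds
  pts <- t(vapply(1:400, function(s)
    systematic_random_sites(c(2, 2), 1, seed = s)[1, ], numeric(2)))
  quad <- 1 + (pts[, 1] > 1) + 2 * (pts[, 2] > 1)
  pv <- suppressWarnings(stats::chisq.test(tabulate(quad, 4)))$p.value
  expect_gt(pv, 0.01)
})
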