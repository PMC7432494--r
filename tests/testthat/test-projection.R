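test_that("composite coordinates scale only the nitrogen axis", {
  expect_equal(composite_coords(c(9.05, 127.1), alpha_N = 0.14),
               c(9.05, 17.794))
  expect_equal(composite_coords(c(9.05, 127.1), alpha_N = 1), c(9.05, 127.1))
  expect_equal(composite_coords(c(0, 0), alpha_N = 0.37), c(0, 0))
})

test_that("exactly collinear observations recover the construction ratio", {
  open <- c(8.50, 120.00); closed <- c(8.00, 118.00)
  obs <- open + 0.24 * (closed - open)
  r <- project_fraction(open, closed, obs)
  expect_equal(r$f_closed, 0.24, tolerance = 1e-12)
  expect_equal(r$f_open, 0.76, tolerance = 1e-12)
  expect_equal(r$perp_deviation, 0, tolerance = 1e-12)
  expect_equal(r$flag, "ok")

  # endpoint identities
  expect_equal(project_fraction(open, closed, open)$f_open, 1)
  expect_equal(project_fraction(open, closed, closed)$f_closed, 1)

  # any t in [0,1], random geometry, recovered to 1e-12
  set.seed(7)
  for (i in 1:50) {
    a <- c(runif(1, 7, 10), runif(1, 105, 130))
    b <- a + c(runif(1, 0.1, 0.5) * sign(runif(1) - 0.5),
               runif(1, 0.5, 2) * sign(runif(1) - 0.5))
    t <- runif(1)
    r <- project_fraction(a, b, a + t * (b - a))
    expect_equal(r$f_closed, t, tolerance = 1e-12)
    expect_equal(r$f_open + r$f_closed, 1)
  }
})

test_that("orthogonal projection agrees with the grid-search oracle", {
  # frozen case computed with the oracle (step 1e-6 over [-0.5, 1.5])
  r <- project_fraction(c(8.50, 120.00), c(8.00, 118.00), c(8.38, 119.60),
                        alpha_N = 0.14)
  expect_equal(r$f_closed, 0.2304507, tolerance = 1e-5)
  expect_equal(r$perp_deviation, 0.0097721, tolerance = 1e-5)

  set.seed(11)
  for (i in 1:5) {
    a <- c(runif(1, 7, 10), runif(1, 105, 130))
    b <- a + c(runif(1, 0.2, 0.5), runif(1, 0.8, 2))
    p <- a + runif(1, -0.3, 1.3) * (b - a) + c(runif(1, -0.02, 0.02),
                                               runif(1, -0.1, 0.1))
    oracle <- grid_search_fraction(a, b, p)
    r <- project_fraction(a, b, p)
    expect_equal(r$f_closed, oracle$t, tolerance = 1e-5)
    expect_equal(r$perp_deviation, oracle$dist, tolerance = 1e-5)
  }
})

test_that("dividing ratios of collinear triples are affine-invariant", {
  set.seed(23)
  for (i in 1:20) {
    a <- c(runif(1, 7, 10), runif(1, 105, 130))
    b <- a + c(runif(1, 0.1, 0.5), runif(1, 0.5, 2))
    t <- runif(1)
    p <- a + t * (b - a)
    # anisotropic rescale + translation of both axes
    sx <- runif(1, 0.2, 5); sy <- runif(1, 0.2, 5)
    dx <- runif(1, -3, 3); dy <- runif(1, -20, 20)
    tf <- function(q) c(sx * q[1] + dx, sy * q[2] + dy)
    r0 <- project_fraction(a, b, p)
    r1 <- project_fraction(tf(a), tf(b), tf(p))
    expect_equal(r1$f_closed, r0$f_closed, tolerance = 1e-10)
  }
})

test_that("moving the observed peak toward the closed reference never decreases f_closed", {
  set.seed(31)
  a <- c(8.7, 112); b <- c(8.3, 113.5)
  ts <- sort(runif(30, -0.2, 1.2))
  fc <- vapply(ts, function(t) {
    project_fraction(a, b, a + t * (b - a) +
                       c(0.001, 0.01))$f_closed  # fixed off-line offset
  }, numeric(1))
  expect_true(all(diff(fc) >= 0))
})

test_that("degenerate and off-line cases are flagged, not silently used", {
  expect_error(project_fraction(c(8, 120), c(8, 120), c(8, 120)),
               "coincide")
  # references closer than min_separation: uninformative
  r <- project_fraction(c(8, 120), c(8.005, 120.01), c(8.002, 120.005))
  expect_equal(r$flag, "uninformative")
  # orthogonal displacement by half the separation: off the line
  a <- c(8.6, 118); b <- c(8.2, 119.6)
  sep <- sqrt(sum((composite_coords(b) - composite_coords(a))^2))
  p <- simulate_offline_peak(a, b, 0.5 * sep)
  r <- project_fraction(a, b, p)
  expect_equal(r$rel_deviation, 0.5, tolerance = 1e-10)
  expect_equal(r$flag, "off_line")
  # out-of-range raw ratio is reported, flagged at the +-0.05 margin
  r <- project_fraction(a, b, a + 1.2 * (b - a))
  expect_equal(r$f_closed, 1.2, tolerance = 1e-10)
  expect_equal(r$flag, "out_of_range")
})

test_that("single-probe aggregation reproduces the trimer unit fractions", {
  a <- c(8.50, 120.00); b <- c(8.00, 118.00)
  ratios <- c(Ub1 = 0.24, Ub2 = 0.67, Ub3 = 0.53)
  results <- do.call(rbind, lapply(names(ratios), function(u) {
    project_fraction(a, b, a + ratios[[u]] * (b - a),
                     residue_number = 70, unit_label = u)
  }))
  fr <- unit_open_fractions(results, policy = "single_probe",
                            probe_residue = 70)
  expect_equal(fr$open_fraction, c(0.76, 0.33, 0.47), tolerance = 1e-12)
  expect_equal(fr$uncertainty, c(0, 0, 0))
  expect_equal(fr$n_residues, c(1L, 1L, 1L))
})

test_that("weighted-mean aggregation averages usable residues by separation^2", {
  a1 <- c(8.5, 120); b1 <- a1 + c(-0.4, -1.5)   # large separation
  a2 <- c(7.9, 115); b2 <- a2 + c(0.12, 0.6)    # small separation
  mk <- function(a, b, t, res) {
    project_fraction(a, b, a + t * (b - a), residue_number = res,
                     unit_label = "Ub1")
  }
  # identical f_open, different separations: mean of constants
  same <- rbind(mk(a1, b1, 0.4, 8), mk(a2, b2, 0.4, 70))
  fr <- unit_open_fractions(same, policy = "weighted_mean")
  expect_equal(fr$open_fraction, 0.6, tolerance = 1e-12)
  expect_equal(fr$n_residues, 2L)
  # different f_open: result pulled toward the better-separated residue
  mixed <- rbind(mk(a1, b1, 0.2, 8), mk(a2, b2, 0.6, 70))
  fr2 <- unit_open_fractions(mixed, policy = "weighted_mean")
  w <- c(same$separation[1]^2, same$separation[2]^2)
  expect_equal(fr2$open_fraction, sum(w * c(0.8, 0.4)) / sum(w),
               tolerance = 1e-12)
  expect_gt(fr2$uncertainty, 0)
  # missing probe residue is an error under single_probe
  expect_error(unit_open_fractions(mixed[1, ], policy = "single_probe",
                                   probe_residue = 70),
               "no usable probe")
})

test_that("collinearity report excludes exactly the off-line residues", {
  a <- c(8.6, 118); b <- c(8.2, 119.6)
  sep <- sqrt(sum((composite_coords(b) - composite_coords(a))^2))
  on_line <- project_fraction(a, b, a + 0.3 * (b - a),
                              residue_number = 8, unit_label = "Ub1")
  off_line <- project_fraction(a, b, simulate_offline_peak(a, b, 0.5 * sep),
                               residue_number = 70, unit_label = "Ub1")
  results <- rbind(on_line, off_line)

  rep1 <- collinearity_report(results, threshold = 0.1)
  expect_equal(rep1$rel_deviation, c(0, 0.5), tolerance = 1e-10)
  expect_equal(rep1$excluded, c(FALSE, TRUE))
  # threshold 1.0 excludes nothing
  rep2 <- collinearity_report(results, threshold = 1.0)
  expect_false(any(rep2$excluded))
})
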