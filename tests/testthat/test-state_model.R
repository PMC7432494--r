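test_that("state enumeration counts follow the matching numbers of complete graphs", {
  counts <- vapply(2:5, function(n) {
    length(enumerate_states(chain_topology(n))$states)
  }, integer(1))
  expect_equal(counts, c(2L, 4L, 10L, 26L))
  # brute-force oracle over edge subsets, small n
  expect_equal(counts[1:3], vapply(2:4, count_matchings_brute, integer(1)))
})

test_that("the trimer state space carries the canonical A-D labels and open patterns", {
  ss <- enumerate_states(chain_topology(3))
  expect_equal(ss$state_labels, c("A", "B", "C", "D"))
  # A all open; B leaves Ub1 open; C leaves Ub3 open; D (end-to-end) leaves
  # the middle unit Ub2 open
  expect_equal(unname(ss$M[, "A"]), c(1, 1, 1))
  expect_equal(unname(ss$M[, "B"]), c(1, 0, 0))
  expect_equal(unname(ss$M[, "C"]), c(0, 0, 1))
  expect_equal(unname(ss$M[, "D"]), c(0, 1, 0))
  expect_equal(ss$states[[which(ss$state_labels == "D")]],
               matrix(c(1L, 3L), 1, 2), ignore_attr = TRUE)
  # restricting to adjacent contacts removes the end-to-end state
  adj <- enumerate_states(chain_topology(3, rbind(c(1, 2), c(2, 3))))
  expect_equal(length(adj$states), 3L)
})

test_that("forward mapping turns populations into per-unit open fractions", {
  ss <- enumerate_states(chain_topology(3))
  expect_equal(unname(forward_unit_fractions(ss, c(0.28, 0.48, 0.19, 0.05))),
               c(0.76, 0.33, 0.47))
  expect_equal(unname(forward_unit_fractions(ss, c(1, 0, 0, 0))), c(1, 1, 1))
  # K48S-mutant populations
  expect_equal(unname(forward_unit_fractions(ss, c(0.33, 0.37, 0.26, 0.04))),
               c(0.70, 0.37, 0.59))
  expect_error(forward_unit_fractions(ss, c(0.5, 0.5)), "expected 4")
  expect_error(forward_unit_fractions(ss, c(0.9, 0.5, -0.2, -0.2)),
               "nonnegative")
})

test_that("the exact trimer solve reproduces the published population split", {
  ss <- enumerate_states(chain_topology(3))
  sol <- solve_populations(ss, c(0.76, 0.33, 0.47))
  expect_equal(sol$method, "exact")
  expect_equal(unname(sol$populations), c(0.28, 0.48, 0.19, 0.05),
               tolerance = 1e-12)
  expect_true(sol$feasible)
  expect_lt(sol$residual, 1e-12)
  expect_equal(round(100 * unname(sol$populations)), c(28, 48, 19, 5))
})

test_that("boundary and infeasible fraction vectors are handled honestly", {
  ss <- enumerate_states(chain_topology(3))
  expect_equal(unname(solve_populations(ss, c(1, 1, 1))$populations),
               c(1, 0, 0, 0), tolerance = 1e-12)
  # no matching closes all three units at once: exact solution is negative
  # in A and must be reported unclipped with feasible = FALSE
  expect_warning(sol <- solve_populations(ss, c(0, 0, 0), method = "exact"),
                 "negative")
  expect_equal(unname(sol$populations), c(-0.5, 0.5, 0.5, 0.5),
               tolerance = 1e-12)
  expect_false(sol$feasible)
  expect_error(solve_populations(ss, c(0.5, 0.5)), "expected 3")
  expect_error(solve_populations(ss, c(1.5, 0.5, 0.5)), "\\[0, 1\\]")
})

test_that("solve inverts the forward map across the whole simplex", {
  ss <- enumerate_states(chain_topology(3))
  set.seed(5)
  for (i in 1:1000) {
    P <- random_simplex(4)
    f <- forward_unit_fractions(ss, P)
    sol <- suppressWarnings(solve_populations(ss, pmin(1, pmax(0, f))))
    expect_equal(unname(sol$populations), P, tolerance = 1e-10)
    expect_equal(sum(sol$populations), 1, tolerance = 1e-8)
  }
})

test_that("NNLS and exact solver agree on feasible square systems", {
  ss <- enumerate_states(chain_topology(3))
  set.seed(9)
  for (i in 1:25) {
    P <- random_simplex(4)
    f <- forward_unit_fractions(ss, P)
    ex <- solve_populations(ss, f, method = "exact")
    nn <- solve_populations(ss, f, method = "nnls")
    expect_equal(unname(nn$populations), unname(ex$populations),
                 tolerance = 1e-8)
    expect_equal(sum(nn$populations), 1, tolerance = 1e-8)
  }
  # infeasible fractions: NNLS stays on the simplex and reports the misfit
  nn0 <- solve_populations(ss, c(0, 0, 0), method = "nnls")
  expect_equal(sum(nn0$populations), 1, tolerance = 1e-8)
  expect_true(all(nn0$populations >= -1e-8))
  expect_gt(nn0$residual, 0.1)
})

test_that("feasibility bounds collapse when the solution is unique and widen when not", {
  ss3 <- enumerate_states(chain_topology(3))
  b3 <- feasibility_bounds(ss3, c(0.76, 0.33, 0.47))
  expect_equal(b3$min, c(0.28, 0.48, 0.19, 0.05), tolerance = 1e-8)
  expect_equal(b3$max, c(0.28, 0.48, 0.19, 0.05), tolerance = 1e-8)

  ss2 <- enumerate_states(chain_topology(2))
  b2 <- feasibility_bounds(ss2, c(1, 1))
  closed_row <- which(vapply(ss2$states, nrow, integer(1)) == 1)
  expect_equal(b2$min[closed_row], 0, tolerance = 1e-10)
  expect_equal(b2$max[closed_row], 0, tolerance = 1e-10)

  # tetramer: 10 states from 5 constraints, genuinely underdetermined
  ss4 <- enumerate_states(chain_topology(4))
  f4 <- c(0.74, 0.53, 0.36, 0.60)
  b4 <- feasibility_bounds(ss4, f4)
  expect_equal(nrow(b4), 10)
  expect_true(all(b4$max >= b4$min - 1e-10))
  expect_gt(max(b4$max - b4$min), 0.01)
  # every interval contains at least one consistent NNLS solution
  nn <- solve_populations(ss4, f4, method = "nnls")
  expect_true(all(nn$populations >= b4$min - 1e-6 &
                  nn$populations <= b4$max + 1e-6))

  expect_error(feasibility_bounds(ss3, c(0, 0, 0)), "Ub1")
})

test_that("bootstrap intervals are seeded, degenerate at zero noise, and match the delta method", {
  ss <- enumerate_states(chain_topology(3))
  f <- c(0.76, 0.33, 0.47)

  b0 <- bootstrap_populations(ss, f, c(0, 0, 0), n_boot = 200, seed = 4)
  expect_equal(b0$lower, b0$point, tolerance = 1e-12)
  expect_equal(b0$upper, b0$point, tolerance = 1e-12)

  b1 <- bootstrap_populations(ss, f, rep(0.02, 3), n_boot = 2000, seed = 10)
  b2 <- bootstrap_populations(ss, f, rep(0.02, 3), n_boot = 2000, seed = 10)
  expect_identical(b1, b2)

  # P_A = (sum f - 1) / 2, so sd(P_A) = sigma * sqrt(3) / 2; the 95%
  # percentile half-width should be about 1.96 times that
  half <- (b1$upper[1] - b1$lower[1]) / 2
  expect_equal(half, 1.96 * 0.02 * sqrt(3) / 2, tolerance = 0.1)
  expect_equal(b1$point[1], 0.28, tolerance = 1e-10)
})
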