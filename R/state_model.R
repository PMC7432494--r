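#' Chain topology
#'
#' Describes an n-unit Lys48-linked ubiquitin chain. Units are labeled
#' Ub1..Ubn with Ub1 the distal end (free Lys48) and Ubn the proximal end
#' (free C-terminus). `allowed_contacts` lists the unit pairs that may form
#' a closed (hydrophobic-patch shielding) contact; by default all pairs are
#' allowed, which for a trimer includes the non-adjacent "end-to-end"
#' Ub1-Ub3 contact.
#'
#' @param n_units integer >= 2.
#' @param allowed_contacts 2-column matrix of unit index pairs, or NULL for
#'   all pairs.
#' @return object of class `chain_topology` with `n_units`, `labels`,
#'   `allowed_contacts`.
#' @export
chain_topology <- function(n_units, allowed_contacts = NULL) {
  n_units <- as.integer(n_units)
  stopifnot(n_units >= 2)
  if (is.null(allowed_contacts)) {
    allowed_contacts <- t(utils::combn(n_units, 2))
  } else {
    allowed_contacts <- matrix(as.integer(allowed_contacts), ncol = 2)
    if (any(allowed_contacts < 1 | allowed_contacts > n_units) ||
        any(allowed_contacts[, 1] == allowed_contacts[, 2])) {
      stop("chain_topology: invalid contact pair(s)")
    }
    allowed_contacts <- t(apply(allowed_contacts, 1, sort))
  }
  structure(list(n_units = n_units,
                 labels = paste0("Ub", seq_len(n_units)),
                 allowed_contacts = allowed_contacts),
            class = "chain_topology")
}

#' Enumerate the conformational state space of a chain
#'
#' A conformational state is a matching on the chain's units: a set of
#' closed Ub-Ub contacts in which each unit shields its hydrophobic patch
#' against at most one partner. A unit is *open* in a state iff it is
#' unpaired. For a trimer with all contacts allowed this gives exactly four
#' states, labeled as in the conformational-equilibrium cartoon: A (all
#' units open), B (Ub2-Ub3 contact, Ub1 open), C (Ub1-Ub2 contact, Ub3
#' open), and D (the end-to-end Ub1-Ub3 contact leaving the middle Ub2
#' open). For other chain lengths states are labeled S01, S02, ... in order
#' of increasing contact count; the tetramer generalization (10 states) is
#' an extension beyond the published trimer model.
#'
#' @param topology a [chain_topology()].
#' @return object of class `state_space`: `topology`, `states` (list of
#'   2-column pair matrices, the empty matching first), `state_labels`, and
#'   the incidence matrix `M` (`n_units` x `n_states`, `M[i, s]` = 1 iff
#'   unit i is open in state s).
#' @export
enumerate_states <- function(topology) {
  stopifnot(inherits(topology, "chain_topology"))
  n <- topology$n_units
  pairs <- topology$allowed_contacts
  n_pairs <- nrow(pairs)

  matchings <- list(integer(0))  # indices into pairs; empty matching first
  grow <- function(chosen, start) {
    for (k in seq_len(n_pairs)) {
      if (k < start) next
      if (length(chosen) > 0 &&
          length(intersect(as.vector(pairs[chosen, , drop = FALSE]),
                           pairs[k, ])) > 0) next
      matchings[[length(matchings) + 1L]] <<- c(chosen, k)
      grow(c(chosen, k), k + 1L)
    }
  }
  grow(integer(0), 1L)

  # order: by contact count, then lexicographically by pair indices
  ord <- order(lengths(matchings),
               vapply(matchings, function(m) {
                 paste(sprintf("%03d", m), collapse = "")
               }, character(1)))
  matchings <- matchings[ord]

  states <- lapply(matchings, function(m) pairs[m, , drop = FALSE])
  M <- vapply(states, function(st) {
    as.numeric(!(seq_len(n) %in% as.vector(st)))
  }, numeric(n))
  M <- matrix(M, nrow = n)
  rownames(M) <- topology$labels

  labels <- sprintf("S%02d", seq_along(states))
  if (n == 3 && length(states) == 4) {
    # canonical trimer labels: A all-open, B = {Ub2-Ub3}, C = {Ub1-Ub2},
    # D = {Ub1-Ub3} (end-to-end); present in label order
    key <- vapply(states, function(st) {
      paste(as.vector(t(st)), collapse = "-")
    }, character(1))
    labels <- c("A", "B", "C", "D")[match(key, c("", "2-3", "1-2", "1-3"))]
    ord2 <- order(labels)
    states <- states[ord2]
    labels <- labels[ord2]
    M <- M[, ord2, drop = FALSE]
  }
  colnames(M) <- labels
  structure(list(topology = topology, states = states,
                 state_labels = labels, M = M),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space>", x$topology$n_units, "units,",
      length(x$states), "states:\n")
  for (s in seq_along(x$states)) {
    st <- x$states[[s]]
    desc <- if (nrow(st) == 0) "all open" else
      paste(apply(st, 1, function(p) {
        paste0(x$topology$labels[p[1]], "-", x$topology$labels[p[2]])
      }), collapse = ", ")
    cat("  ", x$state_labels[s], ": ", desc, "\n", sep = "")
  }
  invisible(x)
}

#' Forward map: state populations to per-unit open fractions
#'
#' The open fraction of unit i is the summed population of the states in
#' which unit i is unpaired: `f = M %*% P`.
#'
#' @param ss a [state_space()][enumerate_states()].
#' @param populations numeric vector, one population per state; must be
#'   nonnegative and sum to 1.
#' @return named numeric vector of per-unit open fractions.
#' @export
forward_unit_fractions <- function(ss, populations) {
  stopifnot(inherits(ss, "state_space"))
  if (length(populations) != length(ss$states)) {
    stop("forward_unit_fractions: expected ", length(ss$states),
         " populations, got ", length(populations))
  }
  if (any(populations < -1e-8) || abs(sum(populations) - 1) > 1e-6) {
    stop("forward_unit_fractions: populations must be nonnegative and sum to 1")
  }
  drop(ss$M %*% populations)
}

#' Invert per-unit open fractions into state populations
#'
#' Solves `M %*% P = f` subject to the normalization `sum(P) = 1`. For the
#' trimer with all contacts allowed the augmented system is square and
#' nonsingular, so the populations follow exactly (in closed form,
#' `P_A = (sum(f) - 1) / 2` and each paired state follows by subtraction);
#' an exact solution with negative components is returned as-is and flagged
#' infeasible — never silently clipped — because it signals that the
#' four-state model cannot reproduce the measured fractions. For
#' non-square systems (longer chains, restricted contacts) a nonnegative
#' least-squares fit with the normalization enforced is used and the
#' residual reported.
#'
#' @param ss a [state_space()][enumerate_states()].
#' @param fractions per-unit open fractions in [0, 1], one per unit.
#' @param method `"auto"` (exact when the augmented system is square and
#'   well-conditioned, else NNLS), `"exact"`, or `"nnls"`.
#' @return object of class `population_solution`: named `populations`,
#'   `method`, `residual` (Euclidean norm of `M P - f`), `feasible`.
#' @export
solve_populations <- function(ss, fractions, method = c("auto", "exact", "nnls")) {
  stopifnot(inherits(ss, "state_space"))
  method <- match.arg(method)
  M <- ss$M
  n_states <- ncol(M)
  if (length(fractions) != nrow(M)) {
    stop("solve_populations: expected ", nrow(M), " unit fractions, got ",
         length(fractions))
  }
  if (any(fractions < -1e-9 | fractions > 1 + 1e-9)) {
    stop("solve_populations: fractions must lie in [0, 1]")
  }
  A <- rbind(M, rep(1, n_states))
  b <- c(fractions, 1)
  square <- nrow(A) == ncol(A)
  if (method == "auto") {
    method <- if (square && rcond(A) > 1e-10) "exact" else "nnls"
  }
  if (method == "exact") {
    if (!square) stop("solve_populations: exact solve needs a square ",
                      "augmented system (", nrow(A), " equations, ",
                      ncol(A), " states)")
    P <- drop(solve(A, b))
  } else {
    w <- 1e6  # hard weight on the normalization row
    fit <- pracma::lsqnonneg(rbind(M, rep(w, n_states)), c(fractions, w))
    P <- fit$x / sum(fit$x)
  }
  names(P) <- ss$state_labels
  feasible <- all(P >= -1e-8)
  if (!feasible) {
    warning("solve_populations: exact solution has negative population(s); ",
            "the state model cannot reproduce these fractions (reported ",
            "unclipped, feasible = FALSE)")
  }
  residual <- sqrt(sum((drop(M %*% P) - fractions)^2))
  structure(list(populations = P, method = method, residual = residual,
                 feasible = feasible),
            class = "population_solution")
}

#' @export
print.population_solution <- function(x, ...) {
  cat("<population_solution> method =", x$method,
      " residual =", format(x$residual, digits = 3),
      " feasible =", x$feasible, "\n")
  pct <- round(100 * x$populations)
  for (s in names(x$populations)) {
    cat(sprintf("  P_%s = %.4f  (%d%%)\n", s, x$populations[s], pct[s]))
  }
  invisible(x)
}

#' Feasibility intervals for state populations
#'
#' For chains where the unit fractions do not pin down a unique population
#' vector (e.g. the 10-state tetramer), computes for each state the minimum
#' and maximum population over the constraint polytope
#' `{P >= 0, sum(P) = 1, M P = f}` by linear programming. When the system
#' has a unique exact solution every interval collapses to it.
#'
#' @inheritParams solve_populations
#' @return data.frame `state`, `min`, `max`; or, if the polytope is empty,
#'   an error listing the violated unit constraints.
#' @export
feasibility_bounds <- function(ss, fractions) {
  stopifnot(inherits(ss, "state_space"))
  M <- ss$M
  n_states <- ncol(M)
  if (length(fractions) != nrow(M)) {
    stop("feasibility_bounds: expected ", nrow(M), " unit fractions")
  }
  Aeq <- rbind(M, rep(1, n_states))
  beq <- c(fractions, 1)
  # infeasibility pre-check via NNLS residual
  w <- 1e6
  fit <- pracma::lsqnonneg(rbind(M, rep(w, n_states)), c(fractions, w))
  resid <- drop(M %*% (fit$x / sum(fit$x))) - fractions
  if (any(abs(resid) > 1e-6)) {
    bad <- ss$topology$labels[abs(resid) > 1e-6]
    stop("feasibility_bounds: no population vector reproduces the given ",
         "fractions; violated unit constraint(s): ",
         paste(bad, collapse = ", "))
  }
  bounds <- t(vapply(seq_len(n_states), function(s) {
    cc <- numeric(n_states); cc[s] <- 1
    lo <- pracma::linprog(cc, Aeq = Aeq, beq = beq, maxiter = 1000)
    hi <- pracma::linprog(cc, Aeq = Aeq, beq = beq, maxiter = 1000,
                          maximize = TRUE)
    c(lo$fval, hi$fval)
  }, numeric(2)))
  data.frame(state = ss$state_labels,
             min = pmax(0, bounds[, 1]), max = pmin(1, bounds[, 2]),
             stringsAsFactors = FALSE)
}

#' Bootstrap confidence intervals for state populations
#'
#' Propagates per-unit measurement uncertainty into the populations by
#' resampling the unit fractions from independent normal perturbations,
#' re-solving for each draw, and reporting 2.5/97.5 percentile intervals.
#' Deterministic for a given seed.
#'
#' @inheritParams solve_populations
#' @param uncertainties per-unit standard errors (same length as
#'   `fractions`).
#' @param n_boot number of bootstrap draws (>= 100).
#' @param seed integer RNG seed.
#' @return data.frame `state`, `point`, `lower`, `upper`.
#' @export
bootstrap_populations <- function(ss, fractions, uncertainties,
                                  n_boot = 2000, seed = 1L) {
  stopifnot(inherits(ss, "state_space"), n_boot >= 100,
            length(uncertainties) == length(fractions),
            all(uncertainties >= 0))
  point <- solve_populations(ss, fractions)$populations
  n_units <- length(fractions)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  draws <- matrix(stats::rnorm(n_boot * n_units, mean = fractions,
                               sd = uncertainties),
                  nrow = n_units)
  draws <- matrix(pmin(1, pmax(0, draws)), nrow = n_units)
  sols <- apply(draws, 2, function(f) {
    suppressWarnings(solve_populations(ss, f)$populations)
  })
  qs <- apply(sols, 1, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(state = ss$state_labels, point = unname(point),
             lower = qs[1, ], upper = qs[2, ], stringsAsFactors = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
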