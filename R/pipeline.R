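#' Pipeline run configuration
#'
#' Collects and validates everything one analysis run needs: the open and
#' closed reference peak lists, one peak list per chain unit, the chain
#' topology, and the thresholds and policies of the projection and solver
#' stages. Validation happens here, before any computation, so a broken
#' configuration fails fast.
#'
#' @param open_ref_path,closed_ref_path paths to the reference peak lists.
#' @param unit_paths named character vector of per-unit peak-list paths;
#'   names must be the topology's unit labels (Ub1...Ubn).
#' @param topology a [chain_topology()].
#' @param dialect `"sparky"` or `"csv"` (applies to all input lists).
#' @param axis_order Sparky column mapping, see [read_sparky_peaklist()].
#' @param policy,probe_residue aggregation policy, see
#'   [unit_open_fractions()].
#' @param alpha_N,min_separation,rel_dev_threshold projection parameters,
#'   see [project_fraction()].
#' @param solver_method see [solve_populations()].
#' @param n_boot bootstrap draws for uncertainty propagation; 0 disables
#'   the bootstrap.
#' @param seed integer seed for all randomness in the run.
#' @param output_dir directory for result files, or NULL to skip writing.
#' @return validated object of class `run_config`.
#' @export
run_config <- function(open_ref_path, closed_ref_path, unit_paths,
                       topology,
                       dialect = c("sparky", "csv"),
                       axis_order = c("N", "H"),
                       policy = c("single_probe", "weighted_mean"),
                       probe_residue = 70L,
                       alpha_N = 0.14, min_separation = 0.02,
                       rel_dev_threshold = 0.10,
                       solver_method = "auto",
                       n_boot = 0L, seed = 1L,
                       output_dir = NULL) {
  dialect <- match.arg(dialect)
  policy <- match.arg(policy)
  stopifnot(inherits(topology, "chain_topology"),
            alpha_N > 0, min_separation > 0, rel_dev_threshold > 0)
  paths <- c(open_ref = open_ref_path, closed_ref = closed_ref_path,
             unit_paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("run_config: missing input file(s): ",
         paste(missing, collapse = ", "))
  }
  if (!setequal(names(unit_paths), topology$labels)) {
    stop("run_config: unit_paths names must be ",
         paste(topology$labels, collapse = ", "))
  }
  structure(list(open_ref_path = open_ref_path,
                 closed_ref_path = closed_ref_path,
                 unit_paths = unit_paths[topology$labels],
                 topology = topology, dialect = dialect,
                 axis_order = axis_order, policy = policy,
                 probe_residue = as.integer(probe_residue),
                 alpha_N = alpha_N, min_separation = min_separation,
                 rel_dev_threshold = rel_dev_threshold,
                 solver_method = solver_method,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

read_any_peaklist <- function(path, dialect, axis_order, spectrum_id) {
  if (dialect == "sparky") {
    read_sparky_peaklist(path, axis_order = axis_order,
                         spectrum_id = spectrum_id)
  } else {
    read_csv_peaklist(path, spectrum_id = spectrum_id)
  }
}

#' Run the full analysis pipeline
#'
#' Ingest -> project -> aggregate -> solve: reads the reference and
#' per-unit peak lists, pairs the references, computes per-residue dividing
#' ratios and collinearity diagnostics, aggregates them into per-unit open
#' fractions, and inverts those into state populations (with optional
#' bootstrap intervals). If `output_dir` is set, writes
#' `projections.csv`, `unit_fractions.csv`, `populations.csv`,
#' `collinearity.csv`, `summary.txt` (the equation system with the measured
#' numbers substituted), and `config.txt` (the effective configuration).
#' All outputs are deterministic for a given configuration and seed.
#'
#' @param config a [run_config()].
#' @return object of class `run_bundle`: `projections`, `unit_fractions`,
#'   `collinearity`, `solution` (a `population_solution`), `bootstrap`
#'   (or NULL), `topology`, `summary` (character vector of report lines).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  topo <- config$topology
  open_ref <- read_any_peaklist(config$open_ref_path, config$dialect,
                                config$axis_order, "open_ref")
  closed_ref <- read_any_peaklist(config$closed_ref_path, config$dialect,
                                  config$axis_order, "closed_ref")
  refs <- reference_pairs(open_ref, closed_ref, alpha_N = config$alpha_N,
                          min_separation = config$min_separation)

  projections <- do.call(rbind, lapply(topo$labels, function(u) {
    pl <- read_any_peaklist(config$unit_paths[[u]], config$dialect,
                            config$axis_order, u)
    project_peaklist(pl, refs, unit_label = u,
                     alpha_N = config$alpha_N,
                     min_separation = config$min_separation,
                     rel_dev_threshold = config$rel_dev_threshold)
  }))
  collin <- collinearity_report(projections,
                                threshold = config$rel_dev_threshold)
  fractions <- unit_open_fractions(projections, policy = config$policy,
                                   probe_residue = config$probe_residue)
  ss <- enumerate_states(topo)
  solution <- solve_populations(ss, fractions$open_fraction,
                                method = config$solver_method)
  boot <- NULL
  if (config$n_boot >= 100) {
    boot <- bootstrap_populations(ss, fractions$open_fraction,
                                  fractions$uncertainty,
                                  n_boot = config$n_boot,
                                  seed = config$seed)
  }
  summary_lines <- equation_report(ss, fractions, solution)
  bundle <- structure(list(projections = projections,
                           unit_fractions = fractions,
                           collinearity = collin,
                           solution = solution, bootstrap = boot,
                           topology = topo, state_space = ss,
                           summary = summary_lines),
                      class = "run_bundle")
  if (!is.null(config$output_dir)) {
    write_bundle(bundle, config)
  }
  bundle
}

# Echo the unit-fraction equations and the normalization with the measured
# numbers substituted, plus the solved populations at full precision and as
# integer percent.
equation_report <- function(ss, fractions, solution) {
  M <- ss$M
  lab <- ss$state_labels
  lines <- character(0)
  for (i in seq_len(nrow(M))) {
    open_states <- lab[M[i, ] == 1]
    closed_states <- lab[M[i, ] == 0]
    f <- fractions$open_fraction[i]
    lines <- c(lines, sprintf(
      "%s open:closed = %s : %s = %.2f : %.2f",
      rownames(M)[i],
      paste0("P_", open_states, collapse = " + "),
      if (length(closed_states)) paste0("P_", closed_states, collapse = " + ")
      else "0",
      f, 1 - f))
  }
  lines <- c(lines,
             paste(paste0("P_", lab, collapse = " + "), "= 1"),
             "",
             sprintf("solver: %s, residual %.3g, feasible %s",
                     solution$method, solution$residual, solution$feasible))
  P <- solution$populations
  pct <- round(100 * P)
  lines <- c(lines, vapply(seq_along(P), function(s) {
    sprintf("P_%s = %.6f  (%d%%)", lab[s], P[s], pct[s])
  }, character(1)))
  if (length(ss$states) > 4 || ss$topology$n_units > 3) {
    lines <- c(lines, "", paste(
      "note: state spaces beyond the three-unit chain are a",
      "generalization of the published four-state trimer model"))
  }
  lines
}

write_bundle <- function(bundle, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  utils::write.csv(bundle$projections, out("projections.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$unit_fractions, out("unit_fractions.csv"),
                   row.names = FALSE)
  sol <- bundle$solution
  utils::write.csv(data.frame(state = names(sol$populations),
                              population = unname(sol$populations),
                              pct_rounded = round(100 * unname(sol$populations)),
                              feasible = sol$feasible),
                   out("populations.csv"), row.names = FALSE)
  utils::write.csv(bundle$collinearity, out("collinearity.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$bootstrap)) {
    utils::write.csv(bundle$bootstrap, out("bootstrap.csv"),
                     row.names = FALSE)
  }
  writeLines(bundle$summary, out("summary.txt"))
  cfg <- config[setdiff(names(config), "topology")]
  writeLines(c(sprintf("n_units: %d", config$topology$n_units),
               vapply(names(cfg), function(k) {
                 sprintf("%s: %s", k, paste(cfg[[k]], collapse = ", "))
               }, character(1))),
             out("config.txt"))
  invisible(NULL)
}

#' @export
print.run_bundle <- function(x, ...) {
  writeLines(x$summary)
  invisible(x)
}

#' Compare two analysis runs
#'
#' Reports per-state population deltas and per-unit open-fraction deltas
#' between two result bundles with the same chain topology — the
#' mutant-versus-wild-type comparison pattern.
#'
#' @param run_a,run_b `run_bundle` objects (see [run_pipeline()]), or
#'   `population_solution` objects for a populations-only comparison.
#' @return list with `delta_populations` (data.frame: state, a, b,
#'   delta, delta_pct_points = 100 * (b - a)) and, when both bundles carry
#'   unit fractions, `delta_fractions`.
#' @export
compare_runs <- function(run_a, run_b) {
  pop_a <- extract_populations(run_a)
  pop_b <- extract_populations(run_b)
  if (!identical(names(pop_a), names(pop_b))) {
    stop("compare_runs: state spaces differ (",
         length(pop_a), " vs ", length(pop_b), " states)")
  }
  out <- list(delta_populations = data.frame(
    state = names(pop_a), a = unname(pop_a), b = unname(pop_b),
    delta = unname(pop_b - pop_a),
    delta_pct_points = round(100 * unname(pop_b - pop_a)),
    stringsAsFactors = FALSE))
  if (inherits(run_a, "run_bundle") && inherits(run_b, "run_bundle")) {
    if (run_a$topology$n_units != run_b$topology$n_units) {
      stop("compare_runs: topologies differ")
    }
    fa <- run_a$unit_fractions
    fb <- run_b$unit_fractions
    out$delta_fractions <- data.frame(
      unit_label = fa$unit_label,
      a = fa$open_fraction, b = fb$open_fraction,
      delta = fb$open_fraction - fa$open_fraction,
      stringsAsFactors = FALSE)
  }
  out
}

extract_populations <- function(x) {
  if (inherits(x, "run_bundle")) x$solution$populations
  else if (inherits(x, "population_solution")) x$populations
  else if (is.numeric(x) && !is.null(names(x))) x
  else stop("compare_runs: expected run_bundle, population_solution, ",
            "or named numeric vector")
}
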