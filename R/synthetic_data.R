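# Human ubiquitin, UniProt P0CG48 repeat unit (76 aa); used only to attach
# residue codes to synthetic probe peaks.
ub_sequence <- paste0(
  "MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQL",
  "EDGRTLSDYNIQKESTLHLVLRLRGG")

ub_residue_code <- function(residue_number) {
  stopifnot(all(residue_number >= 1), all(residue_number <= 76))
  substring(ub_sequence, residue_number, residue_number)
}

#' Deterministic synthetic reference geometry
#'
#' Builds a fixture of open/closed reference peak positions for a set of
#' probe residues. The geometry is synthetic by construction (the
#' published reference shifts exist only as figures, not tables): each
#' residue gets an open-state position in the amide region and a
#' closed-state position displaced by 0.1-0.5 ppm on 1H and 0.5-2.0 ppm on
#' 15N in a residue-dependent direction, so that reference separations are
#' always informative and no two residues' displacement directions
#' coincide. Fully deterministic: the same residue list always yields the
#' same geometry.
#'
#' @param residues integer vector of probe residue numbers (1-76). The
#'   default is the hydrophobic-patch set Leu8, Ile44, Val70 — the residues
#'   whose amide shifts report on patch shielding.
#' @return data.frame with columns `residue_number`, `residue_code`,
#'   `open_H`, `open_N`, `closed_H`, `closed_N`.
#' @export
default_reference_geometry <- function(residues = c(8L, 44L, 70L)) {
  residues <- as.integer(residues)
  stopifnot(length(residues) >= 1, !anyDuplicated(residues))
  i <- seq_along(residues)
  phi <- (sqrt(5) - 1) / 2
  frac <- function(x) x - floor(x)
  # low-discrepancy sequences keyed to the residue number: deterministic,
  # residue-dependent, and well spread
  u1 <- frac(residues * phi)
  u2 <- frac(residues * phi^2)
  u3 <- frac(residues * phi^3)
  u4 <- frac(residues * phi^4)
  open_H <- 7.3 + 1.4 * u3
  open_N <- 108 + 22 * u4
  quadrant <- (i - 1L) %% 4L
  sign_H <- ifelse(quadrant %in% c(0L, 1L), 1, -1)
  sign_N <- ifelse(quadrant %in% c(0L, 3L), 1, -1)
  d_H <- sign_H * (0.1 + 0.4 * u1)
  d_N <- sign_N * (0.5 + 1.5 * u2)
  data.frame(
    residue_number = residues,
    residue_code = ub_residue_code(residues),
    open_H = open_H, open_N = open_N,
    closed_H = open_H + d_H, closed_N = open_N + d_N,
    stringsAsFactors = FALSE)
}

#' Specification for a synthetic chain experiment
#'
#' Bundles the ground truth and noise model from which
#' [simulate_chain_peaklists()] generates peak lists: a chain topology,
#' true state populations, per-residue reference geometry, and Gaussian
#' peak-position noise. The noise defaults (0.003 ppm on 1H, 0.02 ppm on
#' 15N) are typical HSQC peak-position precision.
#'
#' @param topology a [chain_topology()].
#' @param true_populations numeric vector on the simplex, one value per
#'   state of `enumerate_states(topology)`.
#' @param reference_geometry data.frame as returned by
#'   [default_reference_geometry()].
#' @param sigma_H,sigma_N Gaussian peak-position noise, ppm (>= 0).
#' @param seed integer governing all draws.
#' @param exchange_broadening if TRUE, attach to each chain peak an
#'   intensity attenuated in proportion to `f_open * (1 - f_open)`, a
#'   qualitative stand-in for exchange broadening at intermediate
#'   populations.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(topology,
                           true_populations,
                           reference_geometry = default_reference_geometry(),
                           sigma_H = 0.003, sigma_N = 0.02,
                           seed = 1L,
                           exchange_broadening = FALSE) {
  stopifnot(inherits(topology, "chain_topology"),
            sigma_H >= 0, sigma_N >= 0)
  ss <- enumerate_states(topology)
  if (length(true_populations) != length(ss$states)) {
    stop("synthetic_spec: expected ", length(ss$states), " populations")
  }
  if (any(true_populations < 0) || abs(sum(true_populations) - 1) > 1e-8) {
    stop("synthetic_spec: true_populations must be nonnegative and sum to 1")
  }
  structure(list(topology = topology, state_space = ss,
                 true_populations = true_populations,
                 reference_geometry = reference_geometry,
                 sigma_H = sigma_H, sigma_N = sigma_N,
                 seed = as.integer(seed),
                 exchange_broadening = exchange_broadening),
            class = "synthetic_spec")
}

#' Simulate reference and per-unit chain peak lists
#'
#' Realizes the fast-exchange observation model the analysis assumes: each
#' unit's peak for each probe residue is placed at the population-weighted
#' average of the open and closed reference positions,
#' `open + f_closed * (closed - open)` with
#' `f_closed = 1 - f_open(unit)`, plus independent Gaussian position noise.
#' The open and closed reference lists are emitted noise-free (references
#' come from separate, well-resolved spectra of pure species). Fully
#' deterministic given the spec's seed; each unit draws from its own
#' substream so unit lists are independent of list order.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `units` (named list of [peak_list()], one per
#'   chain unit), `open_ref`, `closed_ref` (reference peak lists), and
#'   `truth` (the generating populations and per-unit open fractions).
#' @export
simulate_chain_peaklists <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  geo <- spec$reference_geometry
  f_open <- forward_unit_fractions(spec$state_space, spec$true_populations)
  labels <- spec$topology$labels

  mk_ref <- function(H, N, id) {
    peak_list(data.frame(residue_number = geo$residue_number,
                         residue_code = geo$residue_code,
                         shift_H = H, shift_N = N,
                         stringsAsFactors = FALSE),
              spectrum_id = id)
  }
  open_ref <- mk_ref(geo$open_H, geo$open_N, "open_ref")
  closed_ref <- mk_ref(geo$closed_H, geo$closed_N, "closed_ref")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  units <- stats::setNames(vector("list", length(labels)), labels)
  for (i in seq_along(labels)) {
    set.seed(spec$seed + i)  # per-unit substream
    fc <- 1 - f_open[i]
    H <- geo$open_H + fc * (geo$closed_H - geo$open_H) +
      stats::rnorm(nrow(geo), 0, spec$sigma_H)
    N <- geo$open_N + fc * (geo$closed_N - geo$open_N) +
      stats::rnorm(nrow(geo), 0, spec$sigma_N)
    intensity <- if (spec$exchange_broadening) {
      rep(1 - 2 * f_open[i] * (1 - f_open[i]), nrow(geo))
    } else NA_real_
    units[[i]] <- peak_list(
      data.frame(residue_number = geo$residue_number,
                 residue_code = geo$residue_code,
                 shift_H = H, shift_N = N, intensity = intensity,
                 stringsAsFactors = FALSE),
      spectrum_id = labels[i])
  }
  list(units = units, open_ref = open_ref, closed_ref = closed_ref,
       truth = list(populations = stats::setNames(
                      spec$true_populations, spec$state_space$state_labels),
                    unit_open_fractions = f_open))
}

#' Write a simulated experiment to disk
#'
#' Emits one peak-list file per unit plus the two reference lists, in
#' either dialect, and a `truth.json`-style ground-truth file (written as
#' plain CSV to stay dependency-free) for test harnesses.
#'
#' @param sim result of [simulate_chain_peaklists()].
#' @param dir output directory (created if needed).
#' @param dialect `"sparky"` or `"csv"`.
#' @return named character vector of the written file paths, invisibly.
#' @export
write_chain_peaklists <- function(sim, dir, dialect = c("sparky", "csv")) {
  dialect <- match.arg(dialect)
  ext <- if (dialect == "sparky") ".list" else ".csv"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(open_ref = file.path(dir, paste0("open_ref", ext)),
             closed_ref = file.path(dir, paste0("closed_ref", ext)))
  write_peaklist(sim$open_ref, paths["open_ref"], dialect)
  write_peaklist(sim$closed_ref, paths["closed_ref"], dialect)
  for (u in names(sim$units)) {
    p <- file.path(dir, paste0(u, ext))
    write_peaklist(sim$units[[u]], p, dialect)
    paths[u] <- p
  }
  truth <- data.frame(quantity = c(
    paste0("P_", names(sim$truth$populations)),
    paste0("f_open_", names(sim$truth$unit_open_fractions))),
    value = c(unname(sim$truth$populations),
              unname(sim$truth$unit_open_fractions)))
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  paths["truth"] <- truth_path
  invisible(paths)
}

#' Place a peak off the reference line (negative control)
#'
#' Returns a synthetic observed position displaced orthogonally from the
#' midpoint of the open-closed reference segment by a given composite-ppm
#' offset — a controlled violation of the collinearity assumption, used to
#' exercise the off-line diagnostics.
#'
#' @param open_ref,closed_ref numeric length-2 `c(shift_H, shift_N)` ppm.
#' @param orthogonal_offset composite-ppm displacement (>= 0).
#' @param alpha_N 15N weight.
#' @return numeric length-2 `c(shift_H, shift_N)` in ppm.
#' @export
simulate_offline_peak <- function(open_ref, closed_ref, orthogonal_offset,
                                  alpha_N = 0.14) {
  stopifnot(orthogonal_offset >= 0)
  a <- composite_coords(open_ref, alpha_N)
  b <- composite_coords(closed_ref, alpha_N)
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len == 0) stop("simulate_offline_peak: coincident references")
  normal <- c(-d[2], d[1]) / len
  p <- (a + b) / 2 + orthogonal_offset * normal
  c(p[1], p[2] / alpha_N)
}
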