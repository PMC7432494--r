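#' Composite chemical-shift coordinates
#'
#' Maps an amide (1H, 15N) shift pair onto the plane `(dH, alpha_N * dN)`
#' so that Euclidean distances are comparable across the two nuclei. The
#' weight compensates for the roughly sevenfold larger ppm dispersion of
#' 15N; 0.14 is the common convention for amide chemical-shift
#' perturbation analysis. For exactly collinear peak triples the dividing
#' ratio is invariant to this weight, so it only affects noisy projections
#' and the deviation diagnostics.
#'
#' @param peak numeric length-2 vector `c(shift_H, shift_N)` in ppm.
#' @param alpha_N positive 15N weighting factor.
#' @return numeric length-2 vector of scaled coordinates.
#' @export
composite_coords <- function(peak, alpha_N = 0.14) {
  stopifnot(length(peak) == 2, is.finite(peak), alpha_N > 0)
  c(peak[1], alpha_N * peak[2])
}

#' Pair open and closed reference spectra by residue
#'
#' Matches residues present in both the open-state reference (monomeric Ub)
#' and closed-state reference (cyclic diUb) peak lists and computes the
#' composite-ppm separation of each reference pair. Residues whose
#' references are closer than `min_separation` carry too little shift
#' dispersion to divide and are flagged unusable.
#'
#' @param open_ref,closed_ref [peak_list()] objects for the open and closed
#'   reference states.
#' @param alpha_N 15N weight for composite distances (see
#'   [composite_coords()]).
#' @param min_separation minimum informative reference separation,
#'   composite ppm.
#' @return data.frame with one row per shared residue: reference positions,
#'   `separation`, and logical `usable`.
#' @export
reference_pairs <- function(open_ref, closed_ref, alpha_N = 0.14,
                            min_separation = 0.02) {
  stopifnot(inherits(open_ref, "peak_list"), inherits(closed_ref, "peak_list"))
  shared <- intersect(open_ref$peaks$residue_number,
                      closed_ref$peaks$residue_number)
  op <- open_ref$peaks[match(shared, open_ref$peaks$residue_number), ]
  cl <- closed_ref$peaks[match(shared, closed_ref$peaks$residue_number), ]
  sep <- sqrt((op$shift_H - cl$shift_H)^2 +
              (alpha_N * (op$shift_N - cl$shift_N))^2)
  data.frame(
    residue_number = shared,
    residue_code = op$residue_code,
    open_H = op$shift_H, open_N = op$shift_N,
    closed_H = cl$shift_H, closed_N = cl$shift_N,
    separation = sep,
    usable = sep >= min_separation,
    stringsAsFactors = FALSE)
}

#' Dividing ratio of an observed peak between two reference peaks
#'
#' Under fast exchange between an open and a closed conformer, a residue's
#' HSQC peak sits at the population-weighted average of the two pure-state
#' positions, i.e. on the straight line joining the open-state and
#' closed-state reference peaks. The fraction of the closed state equals
#' the internal division ratio of that segment. This function computes the
#' ratio as the orthogonal-projection parameter `t` of the observed peak
#' onto the reference line in composite coordinates (`t` = 0 at the open
#' reference, 1 at the closed reference), together with the orthogonal
#' residual, which measures how far the peak deviates from the line — the
#' quality check that disqualifies unsuitable references.
#'
#' @param open_ref,closed_ref,observed numeric length-2 vectors
#'   `c(shift_H, shift_N)` in ppm.
#' @param alpha_N 15N weight.
#' @param min_separation composite-ppm threshold below which the reference
#'   pair is uninformative.
#' @param rel_dev_threshold relative orthogonal deviation above which the
#'   observation is flagged `off_line`.
#' @param residue_number,unit_label identifiers carried through to the
#'   result row.
#' @return one-row data.frame (class `projection_result`): `f_closed` (the
#'   raw, unclamped ratio `t`), `f_open` = 1 - t, `perp_deviation`
#'   (composite ppm), `rel_deviation`, `separation`, and a `flag` among
#'   `ok`, `off_line`, `out_of_range`, `uninformative`.
#' @export
project_fraction <- function(open_ref, closed_ref, observed,
                             alpha_N = 0.14, min_separation = 0.02,
                             rel_dev_threshold = 0.10,
                             residue_number = NA_integer_,
                             unit_label = NA_character_) {
  a <- composite_coords(open_ref, alpha_N)
  b <- composite_coords(closed_ref, alpha_N)
  p <- composite_coords(observed, alpha_N)
  d <- b - a
  sep <- sqrt(sum(d^2))
  if (sep == 0) {
    stop("project_fraction: open and closed references coincide (residue ",
         residue_number, ")")
  }
  t <- sum((p - a) * d) / sum(d^2)
  perp <- sqrt(max(0, sum((p - a)^2) - (t * sep)^2))
  rel <- perp / sep
  flag <- if (sep < min_separation) "uninformative"
          else if (rel > rel_dev_threshold) "off_line"
          else if (t < -0.05 || t > 1.05) "out_of_range"
          else "ok"
  res <- data.frame(
    residue_number = as.integer(residue_number),
    unit_label = unit_label,
    f_closed = t, f_open = 1 - t,
    perp_deviation = perp, rel_deviation = rel,
    separation = sep, flag = flag,
    stringsAsFactors = FALSE)
  class(res) <- c("projection_result", class(res))
  res
}

#' Project every usable residue of one unit's spectrum
#'
#' @param observed a [peak_list()] for one chain unit (unit-selectively
#'   labeled spectrum).
#' @param refs reference table from [reference_pairs()].
#' @param unit_label chain-unit identifier (e.g. `"Ub1"`).
#' @inheritParams project_fraction
#' @return data.frame of projection results, one row per residue present in
#'   both `observed` and `refs`.
#' @export
project_peaklist <- function(observed, refs, unit_label,
                             alpha_N = 0.14, min_separation = 0.02,
                             rel_dev_threshold = 0.10) {
  stopifnot(inherits(observed, "peak_list"))
  shared <- intersect(observed$peaks$residue_number, refs$residue_number)
  rows <- lapply(shared, function(r) {
    ob <- observed$peaks[observed$peaks$residue_number == r, ]
    rf <- refs[refs$residue_number == r, ]
    project_fraction(
      open_ref = c(rf$open_H, rf$open_N),
      closed_ref = c(rf$closed_H, rf$closed_N),
      observed = c(ob$shift_H, ob$shift_N),
      alpha_N = alpha_N, min_separation = min_separation,
      rel_dev_threshold = rel_dev_threshold,
      residue_number = r, unit_label = unit_label)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- project_fraction(c(8, 120), c(8.1, 121), c(8, 120))[0, ]
  }
  out
}

#' Per-unit open fractions from projection results
#'
#' Aggregates residue-level dividing ratios into one open fraction per
#' chain unit. The default `single_probe` policy reports the ratio of a
#' single well-resolved probe residue (Val70, on the hydrophobic patch, is
#' the canonical choice); `weighted_mean` averages all non-excluded
#' residues weighted by the squared reference separation, which
#' downweights poorly dispersed probes, and reports a weighted standard
#' error. Raw ratios slightly outside [0, 1] (noise around a nearly pure
#' state) are clamped here — and only here — so that downstream solvers
#' receive feasible inputs, while the residue-level table keeps the raw
#' values for diagnostics.
#'
#' @param results data.frame of projection results (rows from
#'   [project_fraction()], any number of units).
#' @param policy `"single_probe"` or `"weighted_mean"`.
#' @param probe_residue residue number used by `single_probe`.
#' @param clamp clamp unit fractions into [0, 1] (default TRUE).
#' @return data.frame (class `unit_fractions`): `unit_label`,
#'   `open_fraction`, `uncertainty`, `n_residues`.
#' @export
unit_open_fractions <- function(results,
                                policy = c("single_probe", "weighted_mean"),
                                probe_residue = 70L, clamp = TRUE) {
  policy <- match.arg(policy)
  usable <- results[results$flag %in% c("ok", "out_of_range"), , drop = FALSE]
  units <- unique(results$unit_label)
  rows <- lapply(units, function(u) {
    ru <- usable[usable$unit_label == u, , drop = FALSE]
    if (policy == "single_probe") {
      ru <- ru[ru$residue_number == probe_residue, , drop = FALSE]
      if (nrow(ru) == 0) {
        stop("unit_open_fractions: no usable probe residue ", probe_residue,
             " for unit ", u)
      }
      f <- ru$f_open
      se <- 0
      n <- 1L
    } else {
      ok <- ru[ru$flag == "ok", , drop = FALSE]
      if (nrow(ok) == 0) {
        stop("unit_open_fractions: no usable residues for unit ", u)
      }
      w <- ok$separation^2
      f <- sum(w * ok$f_open) / sum(w)
      n <- nrow(ok)
      se <- if (n > 1) {
        sqrt(sum(w * (ok$f_open - f)^2) / sum(w) / (n - 1))
      } else 0
    }
    if (clamp) f <- min(1, max(0, f))
    data.frame(unit_label = u, open_fraction = f, uncertainty = se,
               n_residues = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("unit_fractions", class(out))
  out
}

#' Collinearity quality report
#'
#' Lists, per residue and unit, the relative orthogonal deviation of the
#' observed peak from the open-closed reference line and whether the
#' residue is excluded from aggregation at the given threshold. A large
#' deviation means the two-reference fast-exchange model does not describe
#' that residue (for instance when an unsuitable closed-state reference is
#' used), and the residue must not contribute to unit fractions.
#'
#' @param results data.frame of projection results.
#' @param threshold relative-deviation exclusion threshold.
#' @return data.frame: `unit_label`, `residue_number`, `rel_deviation`,
#'   `separation`, `flag`, `excluded`.
#' @export
collinearity_report <- function(results, threshold = 0.10) {
  data.frame(
    unit_label = results$unit_label,
    residue_number = results$residue_number,
    rel_deviation = results$rel_deviation,
    separation = results$separation,
    flag = results$flag,
    excluded = results$rel_deviation > threshold |
      results$flag == "uninformative",
    stringsAsFactors = FALSE)
}
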