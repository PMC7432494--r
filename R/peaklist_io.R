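#' Assigned 2D peak lists
#'
#' A `peak_list` holds assigned backbone amide resonances from a single
#' 1H-15N HSQC spectrum: one row per residue with the 1H and 15N chemical
#' shifts in ppm. Peak lists are the raw observable of the whole analysis;
#' everything downstream (projection, state populations) consumes them.
#'
#' @param peaks data.frame with columns `residue_number`, `residue_code`,
#'   `shift_H`, `shift_N`, and optionally `intensity`.
#' @param spectrum_id free-text identifier for the spectrum.
#' @param h_window,n_window numeric length-2 sanity windows (ppm) for the 1H
#'   and 15N shifts; peaks outside them are rejected.
#' @return An object of class `peak_list`: a list with elements `spectrum_id`
#'   and `peaks` (a data.frame, one row per residue).
#' @export
peak_list <- function(peaks, spectrum_id = "",
                      h_window = c(0, 15), n_window = c(90, 140)) {
  required <- c("residue_number", "residue_code", "shift_H", "shift_N")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols) > 0) {
    stop("peak_list: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  if (!"intensity" %in% names(peaks)) {
    peaks[["intensity"]] <- rep(NA_real_, nrow(peaks))
  }
  peaks$residue_number <- as.integer(peaks$residue_number)
  peaks$shift_H <- as.numeric(peaks$shift_H)
  peaks$shift_N <- as.numeric(peaks$shift_N)
  if (nrow(peaks) > 0) {
    if (any(peaks$residue_number < 1L)) {
      stop("peak_list: residue_number must be >= 1")
    }
    dup <- peaks$residue_number[duplicated(peaks$residue_number)]
    if (length(dup) > 0) {
      stop("peak_list: duplicate assignment for residue(s) ",
           paste(unique(dup), collapse = ", "))
    }
    bad_h <- peaks$shift_H < h_window[1] | peaks$shift_H > h_window[2]
    bad_n <- peaks$shift_N < n_window[1] | peaks$shift_N > n_window[2]
    if (any(bad_h | bad_n)) {
      stop("peak_list: shift outside sanity window for residue(s) ",
           paste(peaks$residue_number[bad_h | bad_n], collapse = ", "))
    }
    peaks <- peaks[order(peaks$residue_number), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(spectrum_id = spectrum_id, peaks = peaks),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat("<peak_list>", if (nzchar(x$spectrum_id)) x$spectrum_id else "(unnamed)",
      "-", nrow(x$peaks), "assigned peak(s)\n")
  if (nrow(x$peaks) > 0) print(utils::head(x$peaks, 10))
  invisible(x)
}

# Backbone amide assignment token, e.g. "V70N-H".
.sparky_token_re <- "^([A-Za-z])([0-9]+)N-H$"

#' Read a Sparky-style peak list
#'
#' Parses the whitespace-delimited text peak lists exported by Sparky: one
#' line per peak, an assignment token such as `V70N-H` followed by the two
#' axis positions in ppm. Header lines (starting with `Assignment` or `#`)
#' and blank lines are skipped. Tokens that are not backbone amide
#' assignments (sidechain peaks, unassigned peaks) are skipped with a
#' warning rather than an error.
#'
#' @param path path to the `.list` file.
#' @param axis_order character vector of length 2 mapping the two shift
#'   columns (w1, w2) to nuclei; must be a permutation of `c("N", "H")`.
#'   15N is conventionally w1 in 1H-15N HSQC lists, but the mapping is an
#'   explicit, mandatory declaration because exported conventions vary.
#' @param spectrum_id identifier stored on the returned list; defaults to
#'   the file name.
#' @return A [peak_list()].
#' @export
read_sparky_peaklist <- function(path, axis_order = c("N", "H"),
                                 spectrum_id = basename(path)) {
  if (!file.exists(path)) stop("read_sparky_peaklist: no such file: ", path)
  axis_order <- match.arg_axis(axis_order)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  skipped <- character(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (grepl("^(Assignment|#)", line)) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (length(tok) < 3) {
      stop("read_sparky_peaklist: malformed line ", i, " in ", path,
           " (need assignment + 2 shifts): '", line, "'")
    }
    if (!grepl(.sparky_token_re, tok[1])) {
      skipped <- c(skipped, tok[1])
      next
    }
    w <- suppressWarnings(as.numeric(tok[2:3]))
    if (any(is.na(w))) {
      stop("read_sparky_peaklist: non-numeric shift on line ", i, " in ",
           path, ": '", line, "'")
    }
    code <- toupper(sub(.sparky_token_re, "\\1", tok[1]))
    resno <- as.integer(sub(.sparky_token_re, "\\2", tok[1]))
    shifts <- stats::setNames(w, axis_order)
    intensity <- if (length(tok) >= 4) suppressWarnings(as.numeric(tok[4])) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      residue_number = resno, residue_code = code,
      shift_H = unname(shifts["H"]), shift_N = unname(shifts["N"]),
      intensity = intensity, stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0) {
    warning("read_sparky_peaklist: skipped ", length(skipped),
            " non-backbone token(s): ", paste(unique(skipped), collapse = ", "))
  }
  peaks <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(residue_number = integer(0), residue_code = character(0),
               shift_H = numeric(0), shift_N = numeric(0),
               intensity = numeric(0), stringsAsFactors = FALSE)
  peak_list(peaks, spectrum_id = spectrum_id)
}

match.arg_axis <- function(axis_order) {
  if (length(axis_order) != 2 || !setequal(axis_order, c("N", "H"))) {
    stop("axis_order must be a permutation of c(\"N\", \"H\")")
  }
  axis_order
}

#' Read a CSV peak list
#'
#' CSV dialect: header row with at least `residue_number`, `residue_code`,
#' `shift_H`, `shift_N`; optional `intensity`; extra columns are preserved
#' in the peaks data.frame as metadata.
#'
#' @inheritParams read_sparky_peaklist
#' @return A [peak_list()].
#' @export
read_csv_peaklist <- function(path, spectrum_id = basename(path)) {
  if (!file.exists(path)) stop("read_csv_peaklist: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("residue_number", "residue_code", "shift_H", "shift_N")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("read_csv_peaklist: ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  peak_list(df, spectrum_id = spectrum_id)
}

#' Write a peak list
#'
#' Writes `pl` in either dialect at 4-decimal ppm precision, so that
#' reading the file back reproduces every stored field.
#'
#' @param pl a [peak_list()].
#' @param path output file path.
#' @param dialect `"sparky"` (whitespace text, `Assignment w1 w2` header,
#'   w1 = 15N, w2 = 1H) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path, dialect = c("sparky", "csv")) {
  stopifnot(inherits(pl, "peak_list"))
  dialect <- match.arg(dialect)
  pk <- pl$peaks
  if (dialect == "sparky") {
    with_height <- nrow(pk) > 0 && any(!is.na(pk$intensity))
    header <- sprintf("%18s %8s %8s", "Assignment", "w1", "w2")
    if (with_height) header <- paste(header, sprintf("%12s", "Height"))
    body <- character(0)
    if (nrow(pk) > 0) {
      body <- sprintf("%18s %8.4f %8.4f",
                      paste0(pk$residue_code, pk$residue_number, "N-H"),
                      pk$shift_N, pk$shift_H)
      if (with_height) body <- paste(body, sprintf("%12.4f", pk$intensity))
    }
    writeLines(c(header, body), path)
  } else {
    out <- pk
    out$shift_H <- sprintf("%.4f", out$shift_H)
    out$shift_N <- sprintf("%.4f", out$shift_N)
    if (all(is.na(out$intensity))) out$intensity <- NULL
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
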