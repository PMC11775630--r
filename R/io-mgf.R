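#' Spectrum records
#'
#' A centroided MS2 spectrum with its precursor information, plus an
#' averaged MS1 isotope-peak block used for isotope-pattern verification of
#' crosslink identifications.  Peaks are kept sorted by m/z.
#'
#' @param spectrum_id Unique spectrum identifier within a run.
#' @param run_id Run (raw-file) identifier.
#' @param label_state `"light"` (standard water) or `"heavy"` (H2-18-O
#'   digestion).
#' @param precursor_mz,precursor_z Precursor m/z and charge.
#' @param rt Retention time, minutes.
#' @param fragments Two-column matrix-like of fragment `mz`, `intensity`.
#' @param ms1_peaks Two-column matrix-like of MS1 isotope peaks.
#' @param precursor_intensity Scalar precursor intensity (arbitrary units).
#' @return An object of class `"spectrum_record"`.
#' @export
spectrum_record <- function(spectrum_id, run_id = "run1",
                            label_state = c("light", "heavy"),
                            precursor_mz, precursor_z, rt = 0,
                            fragments = NULL, ms1_peaks = NULL,
                            precursor_intensity = 0) {
  label_state <- match.arg(label_state)
  if (precursor_z < 1) stop("precursor_z must be >= 1")
  if (rt < 0) stop("rt must be >= 0")
  norm_peaks <- function(x, what) {
    if (is.null(x) || NROW(x) == 0)
      return(matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("mz", "intensity"))))
    x <- as.matrix(x)
    colnames(x) <- c("mz", "intensity")
    if (is.unsorted(x[, "mz"])) {
      warning("unsorted ", what, " peaks in spectrum ", spectrum_id,
              "; sorting by m/z")
      x <- x[order(x[, "mz"]), , drop = FALSE]
    }
    x
  }
  structure(list(spectrum_id = as.character(spectrum_id),
                 run_id = as.character(run_id), label_state = label_state,
                 precursor_mz = precursor_mz,
                 precursor_z = as.integer(precursor_z), rt = rt,
                 fragments = norm_peaks(fragments, "fragment"),
                 ms1_peaks = norm_peaks(ms1_peaks, "MS1"),
                 precursor_intensity = precursor_intensity),
            class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum> %s (%s, %s) precursor %.4f/%d+ rt %.2f min, %d fragments\n",
              x$spectrum_id, x$run_id, x$label_state, x$precursor_mz,
              x$precursor_z, x$rt, nrow(x$fragments)))
  invisible(x)
}

fmt_peaklist <- function(m) {
  if (nrow(m) == 0) return("")
  paste(sprintf("%.6f:%.6f", m[, 1], m[, 2]), collapse = ";")
}

parse_peaklist <- function(s) {
  if (!nzchar(s))
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("mz", "intensity"))))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  m <- t(vapply(parts, as.numeric, numeric(2)))
  colnames(m) <- c("mz", "intensity")
  m
}

#' Write spectra to an MGF peak list
#'
#' Standard `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`,
#' `CHARGE` and `RTINSECONDS`; the run identifier, label state, precursor
#' intensity and the averaged MS1 isotope block travel in the user fields
#' `RUNID`, `LABEL`, `PRECINT` and `MS1PEAKS` so that a single file carries
#' everything downstream validation needs.  m/z values are written with six
#' decimals.
#' @param spectra List of [spectrum_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    lines <- c(
      "BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      paste0("RUNID=", sp$run_id),
      paste0("LABEL=", sp$label_state),
      sprintf("PEPMASS=%.6f %.6f", sp$precursor_mz, sp$precursor_intensity),
      sprintf("CHARGE=%d+", sp$precursor_z),
      sprintf("RTINSECONDS=%.3f", sp$rt * 60),
      paste0("MS1PEAKS=", fmt_peaklist(sp$ms1_peaks)),
      if (nrow(sp$fragments))
        sprintf("%.6f %.6f", sp$fragments[, 1], sp$fragments[, 2]),
      "END IONS"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an MGF peak list
#' @param path Path to an MGF file written by [write_mgf()] or compatible.
#' @return List of [spectrum_record()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN/END IONS in ", path)
  spectra <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1):(ends[k] - 1)]
    is_header <- grepl("^[A-Z0-9]+=", block)
    headers <- block[is_header]
    keys <- sub("=.*$", "", headers)
    vals <- sub("^[A-Z0-9]+=", "", headers)
    names(vals) <- keys
    if (!"PEPMASS" %in% keys)
      stop("malformed MGF: block ", k, " has no PEPMASS line")
    pm <- as.numeric(strsplit(vals[["PEPMASS"]], "\\s+")[[1]])
    frag_lines <- block[!is_header & nzchar(block)]
    fragments <- if (length(frag_lines)) {
      m <- t(vapply(strsplit(frag_lines, "\\s+"),
                    function(x) as.numeric(x[1:2]), numeric(2)))
      colnames(m) <- c("mz", "intensity")
      m
    } else NULL
    z <- if ("CHARGE" %in% keys) as.integer(sub("\\+$", "", vals[["CHARGE"]])) else 2L
    spectra[[k]] <- spectrum_record(
      spectrum_id = if ("TITLE" %in% keys) vals[["TITLE"]] else paste0("index", k),
      run_id = if ("RUNID" %in% keys) vals[["RUNID"]] else "run1",
      label_state = if ("LABEL" %in% keys) vals[["LABEL"]] else "light",
      precursor_mz = pm[1], precursor_z = z,
      rt = if ("RTINSECONDS" %in% keys)
        as.numeric(vals[["RTINSECONDS"]]) / 60 else 0,
      fragments = fragments,
      ms1_peaks = if ("MS1PEAKS" %in% keys) parse_peaklist(vals[["MS1PEAKS"]]) else NULL,
      precursor_intensity = if (length(pm) > 1) pm[2] else 0
    )
  }
  spectra
}
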