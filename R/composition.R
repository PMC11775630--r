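#' Elemental compositions
#'
#' An elemental composition is a named integer vector of atom counts over
#' the element species `C, H, N, O, S, P, O18` (heavy oxygen is carried as
#' its own species so that 18-O C-terminal labels are preserved through
#' arithmetic).  Plain compositions must be non-negative; modification
#' deltas may be signed and are created with `signed = TRUE`.
#'
#' @param ... Named atom counts, e.g. `composition(C = 2, H = 5, N = 1, O = 2)`.
#' @param signed Allow negative counts (for modification deltas).
#' @return An object of class `"composition"`.
#' @examples
#' composition(H = 2, O = 1)                    # water
#' composition(H = -2, O = -1, signed = TRUE)   # dehydration delta
#' @export
composition <- function(..., signed = FALSE) {
  counts <- c(...)
  if (length(counts) == 0) counts <- numeric(0)
  if (is.null(names(counts)) && length(counts) > 0)
    stop("composition counts must be named by element")
  bad <- setdiff(names(counts), names(ATOMIC_MASS))
  if (length(bad))
    stop("unknown element species: ", paste(bad, collapse = ", "))
  if (any(counts != round(counts)))
    stop("atom counts must be integers")
  if (!signed && any(counts < 0))
    stop("negative atom count in an unsigned composition")
  full <- stats::setNames(numeric(length(ATOMIC_MASS)), names(ATOMIC_MASS))
  full[names(counts)] <- counts
  structure(full, class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  nz <- x[x != 0]
  if (length(nz) == 0) {
    cat("<empty composition>\n")
  } else {
    cat(paste0(names(nz), ifelse(nz == 1, "", nz), collapse = " "),
        sprintf(" (%.6f Da)\n", monoisotopic_mass(x)))
  }
  invisible(x)
}

as_composition <- function(x) {
  if (inherits(x, "composition")) return(x)
  do.call(composition, c(as.list(x), signed = TRUE))
}

#' Add two compositions
#' @param a,b Compositions (or named count vectors).
#' @return A `"composition"` with element-wise summed counts.
#' @export
comp_add <- function(a, b) {
  a <- as_composition(a); b <- as_composition(b)
  structure(unclass(a) + unclass(b), class = "composition")
}

#' Subtract composition `b` from `a`
#'
#' Errors if any resulting count would be negative: removing atoms that are
#' not present is a chemistry error, not a numeric one.
#' @param a,b Compositions.
#' @return A `"composition"`.
#' @export
comp_subtract <- function(a, b) {
  a <- as_composition(a); b <- as_composition(b)
  res <- unclass(a) - unclass(b)
  if (any(res < 0))
    stop("subtraction yields negative atom count for: ",
         paste(names(res)[res < 0], collapse = ", "))
  structure(res, class = "composition")
}

#' Parse a molecular formula string into a composition
#'
#' Accepts Hill-style strings such as `"C10H17N3O6S"`.  Heavy oxygen is
#' written `"O18x"` is not supported in formula strings; build label
#' compositions with [composition()] directly.
#' @param formula A formula string.
#' @return A `"composition"`.
#' @examples
#' parse_formula("C10H17N3O6S")  # glutathione
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (!grepl("^([A-Z][a-z]?-?[0-9]*)*$", formula))
    stop("malformed formula: ", formula)
  m <- gregexpr("[A-Z][a-z]?(-?[0-9]+)?", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  counts <- numeric(0)
  for (p in parts) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", p)
    n <- sub("^[A-Z][a-z]?", "", p)
    n <- if (nzchar(n)) as.numeric(n) else 1
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + n
  }
  do.call(composition, c(as.list(counts), signed = TRUE))
}

#' Monoisotopic mass
#'
#' Generic monoisotopic mass in daltons; methods exist for compositions,
#' peptidoforms, crosslink species and modification definitions.
#' @param x Object to weigh.
#' @param ... Passed to methods.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(composition(H = 2, O = 1))  # 18.010565
#' @export
monoisotopic_mass <- function(x, ...) UseMethod("monoisotopic_mass")

#' @export
monoisotopic_mass.composition <- function(x, ...) {
  sum(unclass(x) * ATOMIC_MASS[names(x)])
}

#' @export
monoisotopic_mass.numeric <- function(x, ...) {
  monoisotopic_mass(as_composition(x))
}

#' Convert a neutral mass to m/z at a given positive charge
#' @param neutral_mass Neutral monoisotopic mass, Da.
#' @param z Positive integer charge.
#' @return m/z value.
#' @examples
#' mz_from_mass(1000, 1)  # 1001.007276
#' @export
mz_from_mass <- function(neutral_mass, z) {
  if (any(z < 1) || any(z != round(z))) stop("charge must be a positive integer")
  (neutral_mass + z * PROTON_MASS) / z
}

#' Recover a neutral mass from m/z and charge
#' @param mz Observed m/z.
#' @param z Positive integer charge.
#' @return Neutral mass, Da.
#' @export
mass_from_mz <- function(mz, z) {
  if (any(z < 1) || any(z != round(z))) stop("charge must be a positive integer")
  mz * z - z * PROTON_MASS
}

#' Parts-per-million mass error
#' @param observed,theoretical Masses (or m/z) on the same scale.
#' @return Signed error in ppm.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
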