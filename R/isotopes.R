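# Theoretical isotope patterns by polynomial convolution over
# nucleon-offset bins.  Each bin carries total intensity and the
# intensity-weighted mass so that averaged (centroid) peak masses come out
# of the convolution directly.

# distribution: list(I = intensities per offset 0..K, M = sum(I * mass))
conv_dist <- function(a, b, trunc_rel = 1e-10) {
  na <- length(a$I); nb <- length(b$I)
  I <- numeric(na + nb - 1)
  M <- numeric(na + nb - 1)
  ma <- ifelse(a$I > 0, a$M / a$I, 0)
  mb <- ifelse(b$I > 0, b$M / b$I, 0)
  for (i in seq_len(na)) {
    if (a$I[i] == 0) next
    idx <- i + seq_len(nb) - 1
    w <- a$I[i] * b$I
    I[idx] <- I[idx] + w
    M[idx] <- M[idx] + w * (ma[i] + mb)
  }
  keep <- I >= trunc_rel * max(I)
  # never drop interior bins: keep everything up to the last retained bin
  last <- max(which(keep))
  list(I = I[seq_len(last)], M = M[seq_len(last)])
}

element_dist <- function(element) {
  tab <- ISOTOPE_TABLE[[element]]
  offsets <- round(tab[, "mass"] - tab[1, "mass"])
  I <- numeric(max(offsets) + 1)
  M <- numeric(max(offsets) + 1)
  I[offsets + 1] <- tab[, "abundance"]
  M[offsets + 1] <- tab[, "abundance"] * tab[, "mass"]
  list(I = I, M = M)
}

# distribution of n atoms of one element, by binary exponentiation
element_power <- function(element, n, trunc_rel = 1e-10) {
  base <- element_dist(element)
  result <- NULL
  while (n > 0) {
    if (n %% 2 == 1)
      result <- if (is.null(result)) base else conv_dist(result, base, trunc_rel)
    n <- n %/% 2
    if (n > 0) base <- conv_dist(base, base, trunc_rel)
  }
  result
}

#' Theoretical isotope pattern of an elemental composition
#'
#' Convolves the natural isotope distributions of every element in the
#' composition (heavy 18-O label atoms are isotopically pure), truncates to
#' the requested number of peaks and renormalizes intensities to sum 1.
#' Peak masses are abundance-weighted centroids within each nucleon bin.
#'
#' @param comp A non-negative [composition()].
#' @param charge Integer charge; `0` returns neutral masses, `z >= 1`
#'   returns protonated m/z values.
#' @param n_peaks Number of isotope peaks to keep (from the monoisotopic
#'   peak upward).
#' @return An object of class `"isotope_pattern"`: a list with `peaks`
#'   (data.frame of `mass`/`mz` and `intensity`) and `charge`.
#' @examples
#' isotope_pattern(parse_formula("C34H61N11O13S"), charge = 2, n_peaks = 5)
#' @export
isotope_pattern <- function(comp, charge = 0L, n_peaks = 6L) {
  comp <- as_composition(comp)
  if (any(unclass(comp) < 0)) stop("composition must be non-negative")
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  dist <- NULL
  for (el in names(comp)) {
    n <- comp[[el]]
    if (n == 0) next
    d <- element_power(el, n)
    dist <- if (is.null(dist)) d else conv_dist(dist, d)
  }
  if (is.null(dist))  # empty composition: a single massless stick
    dist <- list(I = 1, M = 0)
  k <- min(n_peaks, length(dist$I))
  I <- dist$I[seq_len(k)]
  mass <- ifelse(I > 0, dist$M[seq_len(k)] / I, NA_real_)
  keep <- I > 0
  I <- I[keep]; mass <- mass[keep]
  I <- I / sum(I)
  if (charge >= 1) {
    peaks <- data.frame(mz = (mass + charge * PROTON_MASS) / charge,
                        intensity = I)
  } else {
    peaks <- data.frame(mass = mass, intensity = I)
  }
  structure(list(peaks = peaks, charge = as.integer(charge)),
            class = "isotope_pattern")
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat(sprintf("<isotope_pattern> charge %d, %d peaks\n",
              x$charge, nrow(x$peaks)))
  print(x$peaks, row.names = FALSE)
  invisible(x)
}
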