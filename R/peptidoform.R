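#' Peptidoforms
#'
#' A peptidoform is a peptide sequence with site-resolved modifications and
#' an optional heavy (double 18-O) C-terminus, the unit searched and
#' quantified throughout the pipeline.
#'
#' @param sequence Peptide sequence (uppercase one-letter codes).
#' @param site_mods Named list mapping 1-based position (as name) to a
#'   [modification()] object; at most one modification per position, and
#'   the modification's targets must include the residue at that position.
#' @param c_term_heavy_O Number of 18-O atoms at the C-terminus: 0 or 2.
#' @return An object of class `"peptidoform"`.
#' @examples
#' mods <- built_in_modifications()
#' peptidoform("SPVVSGDTSPR", site_mods = list(`5` = mods[["DHAA[ST]"]]))
#' @export
peptidoform <- function(sequence, site_mods = list(), c_term_heavy_O = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, amino_acids())
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  if (!c_term_heavy_O %in% c(0L, 2L))
    stop("c_term_heavy_O must be 0 or 2")
  if (length(site_mods)) {
    pos <- as.integer(names(site_mods))
    if (anyNA(pos) || any(pos < 1) || any(pos > length(res)))
      stop("modification positions must be within 1..", length(res))
    if (anyDuplicated(pos))
      stop("at most one site modification per position")
    for (i in seq_along(site_mods)) {
      m <- site_mods[[i]]
      if (!inherits(m, "modification"))
        stop("site_mods entries must be modification objects")
      if (length(m$targets) && !res[pos[i]] %in% m$targets)
        stop(sprintf("modification %s cannot sit on residue %s at position %d",
                     m$name, res[pos[i]], pos[i]))
    }
    site_mods <- site_mods[order(pos)]
  }
  structure(list(sequence = sequence, residues = res,
                 site_mods = site_mods,
                 c_term_heavy_O = as.integer(c_term_heavy_O)),
            class = "peptidoform")
}

#' @export
print.peptidoform <- function(x, ...) {
  ann <- x$residues
  for (p in names(x$site_mods))
    ann[as.integer(p)] <- sprintf("%s[%s]", ann[as.integer(p)],
                                  x$site_mods[[p]]$name)
  cat(sprintf("<peptidoform> %s%s  %.6f Da\n", paste(ann, collapse = ""),
              if (x$c_term_heavy_O > 0) " (heavy C-term)" else "",
              monoisotopic_mass(x)))
  invisible(x)
}

#' Elemental composition of a peptidoform
#'
#' Residue formulas plus terminal water, plus every site-modification
#' delta, with 18-O atoms substituted for C-terminal 16-O when the
#' peptidoform carries the heavy label.  Requires every site modification
#' to carry an elemental composition.
#' @param p A [peptidoform()].
#' @return A [composition()].
#' @export
peptide_composition <- function(p) {
  stopifnot(inherits(p, "peptidoform"))
  counts <- colSums(RESIDUE_FORMULA[p$residues, , drop = FALSE])
  comp <- comp_add(do.call(composition, as.list(counts)),
                   composition(H = 2, O = 1))
  for (m in p$site_mods) {
    if (is.null(m$delta_composition))
      stop("modification ", m$name, " has no elemental composition; ",
           "a composition is required to compute an elemental total")
    comp <- comp_add(comp, m$delta_composition)
  }
  if (p$c_term_heavy_O > 0)
    comp <- comp_add(comp, composition(O = -p$c_term_heavy_O,
                                       O18 = p$c_term_heavy_O, signed = TRUE))
  comp
}

#' @export
monoisotopic_mass.peptidoform <- function(x, ...) {
  # residue masses + water + mod deltas; avoids requiring compositions for
  # mass-only modifications
  m <- sum(RESIDUE_MASS[x$residues]) +
    monoisotopic_mass(composition(H = 2, O = 1)) +
    sum(vapply(x$site_mods, `[[`, numeric(1), "delta_mass"))
  m + x$c_term_heavy_O * (ATOMIC_MASS[["O18"]] - ATOMIC_MASS[["O"]])
}

#' Crosslinked peptide species
#'
#' Two peptidoforms joined by a dehydroamino-acid-mediated crosslink: the
#' donor site (the residue that eliminylated, S/T/C) on the alpha chain and
#' the nucleophilic acceptor site (C/K/H) on the beta chain.  The species
#' mass is `mass(alpha) + mass(beta) + crosslinker delta` and is symmetric
#' under exchanging the chains.
#'
#' @param alpha,beta [peptidoform()] objects.
#' @param donor_site 1-based position in `alpha`; residue must be S, T or C.
#' @param acceptor_site 1-based position in `beta`; residue must be C, K or H.
#' @param crosslinker A [modification()] of class `crosslink_delta`.
#' @return An object of class `"crosslink_species"`.
#' @examples
#' mods <- built_in_modifications()
#' xl <- crosslink_species(peptidoform("SPVVSGDTSPR"), peptidoform("CGSKDNIK"),
#'                         donor_site = 5, acceptor_site = 1,
#'                         crosslinker = mods[["XL[ST]"]])
#' mz_from_mass(monoisotopic_mass(xl), 4)
#' @export
crosslink_species <- function(alpha, beta, donor_site, acceptor_site,
                              crosslinker) {
  stopifnot(inherits(alpha, "peptidoform"), inherits(beta, "peptidoform"),
            inherits(crosslinker, "modification"))
  if (crosslinker$mod_class != "crosslink_delta")
    stop("crosslinker must have class crosslink_delta")
  dres <- alpha$residues[donor_site]
  if (is.na(dres) || !dres %in% c("S", "T", "C"))
    stop("donor site must be an eliminylatable residue (S/T/C)")
  ares <- beta$residues[acceptor_site]
  if (is.na(ares) || !ares %in% c("C", "K", "H"))
    stop("acceptor site must be a nucleophilic residue (C/K/H)")
  if (length(crosslinker$targets) && !dres %in% crosslinker$targets)
    stop("crosslinker chemistry does not apply to donor residue ", dres)
  amod <- beta$site_mods[[as.character(acceptor_site)]]
  if (!is.null(amod) && amod$mod_class == "fixed" && ares == "C")
    stop("acceptor cysteine is alkylated and cannot accept a crosslink")
  structure(list(alpha = alpha, beta = beta,
                 donor_site = as.integer(donor_site),
                 acceptor_site = as.integer(acceptor_site),
                 crosslinker = crosslinker),
            class = "crosslink_species")
}

#' @export
monoisotopic_mass.crosslink_species <- function(x, ...) {
  monoisotopic_mass(x$alpha) + monoisotopic_mass(x$beta) +
    x$crosslinker$delta_mass
}

#' @export
print.crosslink_species <- function(x, ...) {
  cat(sprintf("<crosslink> %s(%d) x %s(%d) via %s  %.6f Da\n",
              x$alpha$sequence, x$donor_site, x$beta$sequence,
              x$acceptor_site, x$crosslinker$name, monoisotopic_mass(x)))
  invisible(x)
}

#' Elemental composition of a crosslinked species
#' @param x A [crosslink_species()].
#' @return A [composition()].
#' @export
crosslink_composition <- function(x) {
  stopifnot(inherits(x, "crosslink_species"))
  if (is.null(x$crosslinker$delta_composition))
    stop("crosslinker has no elemental composition")
  comp_add(comp_add(peptide_composition(x$alpha), peptide_composition(x$beta)),
           x$crosslinker$delta_composition)
}
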