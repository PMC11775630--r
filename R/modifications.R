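#' Modification definitions
#'
#' A modification definition couples a name, a chemical class, the residues
#' it may sit on, and a mass delta (with its elemental composition where
#' known).  Classes follow the eliminylation chemistry of dehydroamino
#' acids (DHAAs): `eliminylation` (direct -H2O / -H2S loss), `conjugate`
#' (Michael-addition adducts such as glutathione), `label` (18-O C-terminal
#' label), `fixed` (alkylation), and `crosslink_delta` (the mass the
#' crosslinker contributes to a crosslinked peptide pair).
#'
#' @param name Modification name.
#' @param mod_class One of `"eliminylation"`, `"conjugate"`, `"label"`,
#'   `"fixed"`, `"crosslink_delta"`.
#' @param targets Character vector of residue one-letter codes the
#'   modification can occupy; may be empty only for terminus-attached
#'   classes (`label`) and for `crosslink_delta`.
#' @param delta_composition Optional signed [composition()] of the delta.
#' @param delta_mass Monoisotopic delta mass, Da.  Derived from
#'   `delta_composition` when omitted; when both are given they must agree
#'   to 1e-4 Da.
#' @return An object of class `"modification"`.
#' @examples
#' modification("DHA", "eliminylation", targets = c("S"),
#'              delta_composition = composition(H = -2, O = -1, signed = TRUE))
#' @export
modification <- function(name, mod_class, targets = character(),
                         delta_composition = NULL, delta_mass = NULL) {
  mod_class <- match.arg(mod_class, c("eliminylation", "conjugate", "label",
                                      "fixed", "crosslink_delta"))
  residue_attached <- !mod_class %in% c("label", "crosslink_delta")
  if (residue_attached && length(targets) == 0)
    stop("targets must be non-empty for class ", mod_class)
  if (length(targets)) {
    bad <- setdiff(targets, amino_acids())
    if (length(bad)) stop("unknown target residues: ", paste(bad, collapse = ","))
  }
  if (!is.null(delta_composition)) {
    delta_composition <- as_composition(delta_composition)
    comp_mass <- monoisotopic_mass(delta_composition)
    if (is.null(delta_mass)) delta_mass <- comp_mass
    else if (abs(comp_mass - delta_mass) >= 1e-4)
      stop(sprintf("delta_mass %.6f disagrees with composition mass %.6f",
                   delta_mass, comp_mass))
  }
  if (is.null(delta_mass))
    stop("either delta_composition or delta_mass is required")
  structure(list(name = name, mod_class = mod_class, targets = targets,
                 delta_composition = delta_composition,
                 delta_mass = delta_mass),
            class = "modification")
}

#' @export
print.modification <- function(x, ...) {
  cat(sprintf("<modification> %s [%s] %+0.6f Da on {%s}\n",
              x$name, x$mod_class, x$delta_mass,
              paste(x$targets, collapse = "")))
  invisible(x)
}

#' @export
monoisotopic_mass.modification <- function(x, ...) x$delta_mass

# Nucleophile formulas for the DHAA conjugates.
NUCLEOPHILE_FORMULA <- c(
  GSH  = "C10H17N3O6S",  # glutathione
  HC   = "C4H9NO2S",     # homocysteine
  DTT  = "C4H10O2S2",    # dithiothreitol
  TCEP = "C9H15O6P"      # tris(2-carboxyethyl)phosphine
)

#' Mass delta of eliminylation (DHAA formation)
#'
#' Serine and threonine lose water (dehydroalanine / dehydrobutyrine);
#' cysteine loses hydrogen sulphide.  Phosphorylated precursors eliminate
#' to the same product, so the delta relative to the unmodified residue is
#' identical.
#' @param residue One of `"S"`, `"T"`, `"C"`.
#' @return Signed delta mass in Da (about -18.0106 for S/T, -33.9877 for C).
#' @examples
#' eliminylation_delta("S")
#' eliminylation_delta("C")
#' @export
eliminylation_delta <- function(residue) {
  vapply(residue, function(r) {
    switch(r,
      S = , T = -monoisotopic_mass(composition(H = 2, O = 1)),
      C = -monoisotopic_mass(composition(H = 2, S = 1)),
      stop("residue ", r, " cannot form a dehydroamino acid ",
           "(only S, T and C are eliminylatable)"))
  }, numeric(1), USE.NAMES = FALSE)
}

# Signed composition of the eliminylation delta for a precursor residue.
eliminylation_delta_composition <- function(residue) {
  switch(residue,
    S = , T = composition(H = -2, O = -1, signed = TRUE),
    C = composition(H = -2, S = -1, signed = TRUE),
    stop("residue ", residue, " cannot form a dehydroamino acid"))
}

#' Mass delta of a DHAA nucleophile conjugate
#'
#' The delta relative to the *unmodified* precursor residue: eliminylation
#' first removes H2O (S/T) or H2S (C), then Michael addition adds the full
#' mass of the intact nucleophile.
#' @param conjugate One of `"GSH"`, `"HC"`, `"DTT"`, `"TCEP"`.
#' @param precursor_residue One of `"S"`, `"T"`, `"C"`.
#' @return Signed delta mass, Da.
#' @examples
#' conjugate_delta("GSH", "S")   # +289.073242
#' conjugate_delta("DTT", "C")   # +120.024500
#' @export
conjugate_delta <- function(conjugate, precursor_residue) {
  if (!conjugate %in% names(NUCLEOPHILE_FORMULA))
    stop("unknown conjugate: ", conjugate)
  eliminylation_delta(precursor_residue) +
    monoisotopic_mass(parse_formula(NUCLEOPHILE_FORMULA[[conjugate]]))
}

# Signed composition of a conjugate delta.
conjugate_delta_composition <- function(conjugate, precursor_residue) {
  comp_add(eliminylation_delta_composition(precursor_residue),
           parse_formula(NUCLEOPHILE_FORMULA[[conjugate]]))
}

#' Mass shift from 18-O C-terminal labelling
#'
#' Tryptic digestion in heavy water installs two 18-O atoms at each new
#' C-terminal carboxylate: a nominal +4 Da per labelled terminus, +8 Da for
#' a crosslinked pair of peptides (two termini).
#' @param n_labeled_termini 0, 1 or 2 labelled C-termini.
#' @return Exact mass shift, Da.
#' @examples
#' label_18O_shift(1)  # +4.008490
#' label_18O_shift(2)  # +8.016980
#' @export
label_18O_shift <- function(n_labeled_termini) {
  if (!n_labeled_termini %in% 0:2)
    stop("n_labeled_termini must be 0, 1 or 2")
  n_labeled_termini * 2 * (ATOMIC_MASS[["O18"]] - ATOMIC_MASS[["O"]])
}

#' Built-in modification set
#'
#' The shipped definitions cover the eliminylation chemistry end to end:
#' direct DHAA losses on S/T and C, the four nucleophile conjugates (GSH,
#' HC, DTT, TCEP) on each precursor class, the double 18-O C-terminal
#' label, the carbamidomethyl and propionamide fixed cysteine alkylations,
#' phosphorylation, and the two crosslinker deltas (S/T-derived and
#' C-derived dehydroamino acids).
#' @return Named list of [modification()] objects.
#' @export
built_in_modifications <- function() {
  mods <- list(
    modification("DHAA[ST]", "eliminylation", c("S", "T"),
                 composition(H = -2, O = -1, signed = TRUE)),
    modification("DHAA[C]", "eliminylation", "C",
                 composition(H = -2, S = -1, signed = TRUE)),
    modification("18O-Cterm", "label",
                 delta_composition = composition(O = -2, O18 = 2, signed = TRUE)),
    modification("Carbamidomethyl", "fixed", "C", parse_formula("C2H3NO")),
    modification("Propionamide", "fixed", "C", parse_formula("C3H5NO")),
    modification("Phospho", "fixed", c("S", "T", "Y"), parse_formula("HPO3")),
    modification("XL[ST]", "crosslink_delta", c("S", "T"),
                 composition(H = -2, O = -1, signed = TRUE)),
    modification("XL[C]", "crosslink_delta", "C",
                 composition(H = -2, S = -1, signed = TRUE))
  )
  for (cj in names(NUCLEOPHILE_FORMULA)) {
    mods <- c(mods, list(
      modification(paste0(cj, "-DHAA[ST]"), "conjugate", c("S", "T"),
                   conjugate_delta_composition(cj, "S")),
      modification(paste0(cj, "-DHAA[C]"), "conjugate", "C",
                   conjugate_delta_composition(cj, "C"))
    ))
  }
  stats::setNames(mods, vapply(mods, `[[`, character(1), "name"))
}

#' Read modification definitions from a YAML config
#'
#' Each entry carries `name`, `class`, `targets` (string of one-letter
#' codes, may be empty) and either `formula` (signed formula string such as
#' `"H-2O-1"`) or `delta_mass`.
#' @param path Path to a YAML file.
#' @return Named list of [modification()] objects.
#' @export
read_modifications <- function(path) {
  entries <- yaml::read_yaml(path)
  mods <- lapply(entries, function(e) {
    comp <- if (!is.null(e$formula)) parse_formula(e$formula) else NULL
    targets <- if (is.null(e$targets) || !nzchar(e$targets)) character()
               else strsplit(e$targets, "")[[1]]
    modification(e$name, e$class, targets, comp, e$delta_mass)
  })
  stats::setNames(mods, vapply(mods, `[[`, character(1), "name"))
}

#' Write modification definitions to a YAML config
#' @param mods Named list of [modification()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modifications <- function(mods, path) {
  entries <- lapply(unname(mods), function(m) {
    e <- list(name = m$name, class = m$mod_class,
              targets = paste(m$targets, collapse = ""))
    has_o18 <- !is.null(m$delta_composition) && m$delta_composition[["O18"]] != 0
    if (!is.null(m$delta_composition) && !has_o18) {
      nz <- m$delta_composition[m$delta_composition != 0]
      e$formula <- paste0(names(nz), unclass(nz), collapse = "")
    } else {
      # formula strings cannot express the heavy-oxygen species
      e$delta_mass <- m$delta_mass
    }
    e
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
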