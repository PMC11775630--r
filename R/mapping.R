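#' Map a peptide (and its modified positions) to protein coordinates
#'
#' Finds every occurrence of the peptide in the protein and converts
#' peptide-internal positions to 1-based protein coordinates, the
#' convention used for site names such as "S262" or "C291".
#'
#' @param peptide Peptide sequence.
#' @param protein Protein sequence (or a one-row data.frame with a
#'   `sequence` column).
#' @param positions Integer vector of 1-based peptide positions to map
#'   (e.g. modified sites); may be empty.
#' @return data.frame with one row per (occurrence, position):
#'   columns `start`, `peptide_pos`, `protein_pos`.  With empty
#'   `positions`, one row per occurrence with `peptide_pos`/`protein_pos`
#'   `NA`.  Zero rows when the peptide is absent.
#' @examples
#' map_to_protein("SGDTSPR", "KKSGDTSPRAA", positions = 4)
#' @export
map_to_protein <- function(peptide, protein, positions = integer()) {
  if (is.data.frame(protein)) protein <- protein$sequence[1]
  starts <- c()
  from <- 1
  repeat {  # overlapping occurrences included
    hit <- regexpr(peptide, substr(protein, from, nchar(protein)),
                   fixed = TRUE)
    if (hit == -1) break
    starts <- c(starts, from + hit - 1)
    from <- from + hit
  }
  if (length(starts) == 0)
    return(data.frame(start = integer(), peptide_pos = integer(),
                      protein_pos = integer()))
  if (length(positions) == 0)
    return(data.frame(start = starts, peptide_pos = NA_integer_,
                      protein_pos = NA_integer_))
  out <- expand.grid(peptide_pos = as.integer(positions),
                     start = as.integer(starts))
  data.frame(start = out$start, peptide_pos = out$peptide_pos,
             protein_pos = out$start + out$peptide_pos - 1L)
}

#' Classify a crosslink as intra- or inter-protein
#'
#' A link is `intra` when both peptides map to the same protein accession
#' (the by-accession convention: same-protein links cannot be resolved
#' into intra- vs intermolecular from the mass spectrum alone), `inter`
#' otherwise.
#' @param accession_alpha,accession_beta Accessions of the two chains.
#' @return Character vector of `"intra"` / `"inter"`.
#' @examples
#' classify_link("P10636", "P10636")  # intra (e.g. Tau S262 x Tau C291)
#' classify_link("P04406", "P45880")  # inter (e.g. GAPDH x VDAC2)
#' @export
classify_link <- function(accession_alpha, accession_beta) {
  ifelse(accession_alpha == accession_beta, "intra", "inter")
}
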