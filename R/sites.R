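#' Call eliminylation sites from PSM evidence
#'
#' Aggregates modified PSMs into one record per (accession, protein
#' position).  A site is *confirmed* only when at least one conjugate
#' species (GSH, HC, DTT, TCEP or a crosslink) is observed there: the
#' direct -18/-34 Da loss alone may arise artifactually in the instrument
#' and is retained but flagged unconfirmed.
#'
#' @param psm_sites data.frame with one row per modified-site observation:
#'   columns `accession`, `protein_pos`, `residue`, `evidence_form` (one
#'   of `direct`, `GSH`, `HC`, `DTT`, `TCEP`, `XL`), `specimen_id`.
#' @return data.frame with one row per site: `accession`, `residue`,
#'   `protein_pos`, `evidence_forms` (comma-joined), `n_specimens`,
#'   `specimens` (comma-joined ids), `confirmed`.
#' @export
call_sites <- function(psm_sites) {
  conj_forms <- c("GSH", "HC", "DTT", "TCEP", "XL")
  if (nrow(psm_sites) == 0)
    return(data.frame(accession = character(), residue = character(),
                      protein_pos = integer(), evidence_forms = character(),
                      n_specimens = integer(), specimens = character(),
                      confirmed = logical()))
  key <- paste(psm_sites$accession, psm_sites$protein_pos, sep = "|")
  pieces <- lapply(split(psm_sites, key), function(g) {
    forms <- sort(unique(g$evidence_form))
    specs <- sort(unique(g$specimen_id))
    data.frame(accession = g$accession[1], residue = g$residue[1],
               protein_pos = g$protein_pos[1],
               evidence_forms = paste(forms, collapse = ","),
               n_specimens = length(specs),
               specimens = paste(specs, collapse = ","),
               confirmed = any(forms %in% conj_forms))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$accession, out$protein_pos), ]
  rownames(out) <- NULL
  out
}

#' Specimen-prevalence summary of eliminylation sites
#'
#' Counts sites (and the distinct proteins carrying them) observed in at
#' least a given fraction of specimens, at each threshold.  Thresholds are
#' inclusive, so counts are non-increasing in the threshold.
#'
#' @param sites data.frame from [call_sites()] (uses `n_specimens` and
#'   `accession`; set `confirmed_only = TRUE` to restrict to confirmed
#'   sites).
#' @param n_specimens Total number of specimens analysed.
#' @param thresholds Fractions of specimens (default any / 50 / 80 / 100
#'   percent).
#' @param confirmed_only Restrict to conjugate-confirmed sites.
#' @return data.frame with `threshold`, `n_sites`, `n_proteins`.
#' @export
prevalence_summary <- function(sites, n_specimens,
                               thresholds = c(0, 0.5, 0.8, 1),
                               confirmed_only = FALSE) {
  if (n_specimens <= 0) stop("n_specimens must be positive")
  if (confirmed_only) sites <- sites[sites$confirmed, , drop = FALSE]
  frac <- sites$n_specimens / n_specimens
  out <- lapply(thresholds, function(th) {
    sel <- if (th == 0) rep(TRUE, length(frac)) else frac >= th
    data.frame(threshold = th, n_sites = sum(sel),
               n_proteins = length(unique(sites$accession[sel])))
  })
  do.call(rbind, out)
}

#' Fraction of PTM-bearing proteins found in aggregate-association lists
#'
#' For each PTM group (e.g. all proteins observed with a DHAA conjugate,
#' all phosphorylated proteins) computes the fraction of its members
#' present in the neurofibrillary-tangle and senile-plaque association
#' lists.
#'
#' @param ptm_groups Named list of character accession vectors, one per
#'   PTM type.
#' @param nft_list,sp_list Character accession vectors of
#'   aggregate-associated proteins.
#' @return data.frame with `ptm`, `n_proteins`, `fraction_nft`,
#'   `fraction_sp`.
#' @export
association_fraction <- function(ptm_groups, nft_list, sp_list) {
  if (any(lengths(ptm_groups) == 0)) stop("empty PTM group")
  out <- lapply(names(ptm_groups), function(nm) {
    g <- unique(ptm_groups[[nm]])
    data.frame(ptm = nm, n_proteins = length(g),
               fraction_nft = length(intersect(g, nft_list)) / length(g),
               fraction_sp = length(intersect(g, sp_list)) / length(g))
  })
  do.call(rbind, out)
}
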