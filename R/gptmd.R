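#' Open (delta-mass) modification discovery
#'
#' A GPTMD-style pass: each spectrum is matched against unmodified
#' candidate peptides under a wide precursor window, the unexplained
#' precursor delta is compared with a list of candidate modification
#' deltas, and a matching delta is localized to the candidate's target
#' residue that maximizes the fragment score.  The emitted
#' (protein, site, modification) entries are the raw material for
#' augmenting the search database.
#'
#' @param spectra List of [spectrum_record()] objects.
#' @param proteins Protein database (data.frame as from [read_fasta()]).
#' @param candidates Named list of candidate [modification()]s; typically
#'   the DHAA set (direct -H2O / -H2S losses and the GSH/HC/DTT/TCEP
#'   conjugates) from [built_in_modifications()].
#' @param params A [search_params()]; its precursor tolerance is applied
#'   to the delta match, not to the wide first-pass window.
#' @param min_fragment_score Minimum fragment score for the base peptide
#'   match to be considered confident (default 6).
#' @return data.frame with columns `spectrum_id`, `accession`, `peptide`,
#'   `start`, `peptide_pos`, `protein_pos`, `mod_name`, `delta_mass`,
#'   `score`.
#' @export
discover_delta_mods <- function(spectra, proteins, candidates,
                                params = search_params(),
                                min_fragment_score = 6) {
  index <- build_candidate_index(proteins,
    search_params(precursor_tol_ppm = params$precursor_tol_ppm,
                  fragment_tol_ppm = params$fragment_tol_ppm,
                  fragment_charges = params$fragment_charges,
                  fixed_mods = params$fixed_mods,
                  variable_mods = list(), digest = params$digest,
                  label_state = params$label_state))
  keep <- !index$meta$is_decoy
  cands <- index$candidates[keep]
  meta <- index$meta[keep, , drop = FALSE]
  masses <- meta$mass
  deltas <- vapply(candidates, `[[`, numeric(1), "delta_mass")
  dmin <- min(deltas); dmax <- max(deltas)
  out <- list()
  for (sp in spectra) {
    neutral <- mass_from_mz(sp$precursor_mz, sp$precursor_z)
    # peptides whose mass + some candidate delta could equal the
    # precursor; the window is widened by the largest fixed-mod mass a
    # discovered modification could displace
    lo <- findInterval(neutral - dmax - 0.5, masses) + 1L
    hi <- findInterval(neutral - dmin + 60.5, masses)
    if (hi < lo) next
    for (h in lo:hi) {
      delta_obs <- neutral - masses[h]
      tol <- neutral * params$precursor_tol_ppm * 1e-6
      if (min(abs(deltas - delta_obs)) > tol + 60) next  # fast reject
      pep <- cands[[h]]
      res <- pep$residues
      for (ci in seq_along(candidates)) {
        mod <- candidates[[ci]]
        open <- which(res %in% mod$targets)
        if (length(open) == 0) next
        # a discovered modification displaces any fixed alkylation at its
        # site, so the expected precursor delta is position-dependent
        exp_delta <- vapply(open, function(pos) {
          fx <- pep$site_mods[[as.character(pos)]]
          mod$delta_mass - if (is.null(fx)) 0 else fx$delta_mass
        }, numeric(1))
        open <- open[abs(exp_delta - delta_obs) <= tol]
        if (length(open) == 0) next
        scores <- vapply(open, function(pos) {
          mods <- pep$site_mods
          mods[[as.character(pos)]] <- mod
          pf <- peptidoform(pep$sequence, mods, pep$c_term_heavy_O)
          score_match(sp, theoretical_fragments(pf, params$fragment_charges),
                      params$fragment_tol_ppm)$score
        }, numeric(1))
        best <- which.max(scores)  # ties resolve to the lowest position
        if (scores[best] < min_fragment_score) next
        out[[length(out) + 1L]] <- data.frame(
          spectrum_id = sp$spectrum_id, accession = meta$accession[h],
          peptide = pep$sequence, start = meta$start[h],
          peptide_pos = open[best],
          protein_pos = meta$start[h] + open[best] - 1L,
          mod_name = mod$name, delta_mass = mod$delta_mass,
          score = scores[best])
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(spectrum_id = character(), accession = character(),
                      peptide = character(), start = integer(),
                      peptide_pos = integer(), protein_pos = integer(),
                      mod_name = character(), delta_mass = numeric(),
                      score = numeric()))
  res <- do.call(rbind, out)
  # keep the best-scoring localization per spectrum
  res <- res[order(res$spectrum_id, -res$score, res$peptide_pos), ]
  res <- res[!duplicated(res$spectrum_id), ]
  rownames(res) <- NULL
  res
}
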