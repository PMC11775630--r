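#' End-to-end crosslink discovery with 18-O validation
#'
#' Runs the full workflow on paired light/heavy spectra: crosslink
#' searches under both donor chemistries against a targeted database,
#' heavy/light pairing (+8 Da), MS1 theoretical-isotope verification,
#' full-proteome re-search of the accepted candidates as site-specific
#' custom modifications, and the three-criterion acceptance rule.
#'
#' @param spectra_light,spectra_heavy Lists of [spectrum_record()]s from
#'   paired standard and H2-18-O digestions.
#' @param targeted_db Targeted protein database for the crosslink search.
#' @param full_proteome Full protein database for the criterion-3
#'   re-search.
#' @param search A [search_params()].
#' @param pairing A [pairing_params()].
#' @return List with `evidence` (per-crosslink data.frame incl. the three
#'   criterion columns and `accepted`), `csms_light`, `csms_heavy`.
#' @export
discover_crosslinks <- function(spectra_light, spectra_heavy, targeted_db,
                                full_proteome = targeted_db,
                                search = search_params(),
                                pairing = pairing_params()) {
  search_heavy <- search
  search_heavy$label_state <- "heavy"
  # pool the two chemistry searches with decoys retained, let the best
  # explanation per spectrum win the target-decoy competition, then
  # estimate q-values over the pooled spectrum-level matches
  run_both <- function(spectra, par) {
    pooled <- rbind(
      search_crosslinks(spectra, targeted_db, "ST", params = par,
                        keep_decoys = TRUE),
      search_crosslinks(spectra, targeted_db, "C", params = par,
                        keep_decoys = TRUE))
    if (nrow(pooled) == 0) return(pooled)
    pooled <- pooled[order(pooled$spectrum_id, -pooled$score,
                           pooled$is_decoy), ]
    pooled <- pooled[!duplicated(pooled$spectrum_id), ]
    pooled$q_value <- if (any(!pooled$is_decoy))
      estimate_fdr(pooled$score, pooled$is_decoy) else rep(1, nrow(pooled))
    pooled <- pooled[!pooled$is_decoy &
                       pooled$q_value <= par$fdr_threshold, ]
    pooled$is_decoy <- NULL
    rownames(pooled) <- NULL
    pooled
  }
  csms_light <- dedupe_csms(run_both(spectra_light, search))
  csms_heavy <- dedupe_csms(run_both(spectra_heavy, search_heavy))
  evidence <- pair_heavy_light(csms_light, csms_heavy, pairing)

  # criterion 2: MS1 isotope-pattern and mass verification
  spec_by_id <- stats::setNames(spectra_light,
                                vapply(spectra_light, `[[`, character(1),
                                       "spectrum_id"))
  registry <- built_in_modifications()
  evidence$ms1_similarity <- NA_real_
  evidence$ms1_mass_error_ppm <- NA_real_
  for (i in seq_len(nrow(evidence))) {
    sp <- spec_by_id[[evidence$spectrum_id[i]]]
    if (is.null(sp) || nrow(sp$ms1_peaks) == 0) next
    xl <- evidence_species(evidence[i, ], registry)
    theory <- isotope_pattern(crosslink_composition(xl),
                              charge = sp$precursor_z, n_peaks = 5)
    evidence$ms1_similarity[i] <-
      isotope_similarity(sp$ms1_peaks, theory, pairing$mass_tol_ppm)
    obs_mono <- mass_from_mz(sp$ms1_peaks[1, 1], sp$precursor_z)
    evidence$ms1_mass_error_ppm[i] <-
      ppm_error(obs_mono, monoisotopic_mass(xl))
  }

  # criterion 3: full-proteome re-search with the candidate crosslinks
  # appended as site-specific custom modifications
  evidence$full_proteome_q_light <- NA_real_
  evidence$full_proteome_q_heavy <- NA_real_
  if (nrow(evidence)) {
    xlmods_l <- append_crosslinks_to_database(list(), evidence, "light")
    xlmods_h <- append_crosslinks_to_database(list(), evidence, "heavy")
    par_l <- search; par_l$variable_mods <- xlmods_l
    par_l$fdr_threshold <- 1
    par_h <- search_heavy; par_h$variable_mods <- xlmods_h
    par_h$fdr_threshold <- 1
    psm_l <- search_linear(spectra_light, full_proteome, par_l)
    psm_h <- search_linear(spectra_heavy, full_proteome, par_h)
    q_for <- function(psms, ev_row) {
      # the re-search must re-find the crosslinked species: the alpha
      # peptide carrying the partner-mass modification at the donor site
      hit <- psms[psms$peptide == ev_row$alpha_peptide &
                  grepl("XLmod:", psms$mods, fixed = TRUE) &
                  psms$accession == ev_row$alpha_accession, ]
      if (nrow(hit) == 0) NA_real_ else min(hit$q_value)
    }
    for (i in seq_len(nrow(evidence))) {
      evidence$full_proteome_q_light[i] <- q_for(psm_l, evidence[i, ])
      evidence$full_proteome_q_heavy[i] <- q_for(psm_h, evidence[i, ])
    }
  }
  evidence <- accept_crosslinks(evidence, pairing)
  list(evidence = evidence, csms_light = csms_light,
       csms_heavy = csms_heavy)
}

# one CSM per distinct crosslink (best score) from pooled chemistry runs
dedupe_csms <- function(csms) {
  if (nrow(csms) == 0) return(csms)
  key <- xl_pair_key(csms)
  csms <- csms[order(key, -csms$score), ]
  csms <- csms[!duplicated(xl_pair_key(csms)), ]
  rownames(csms) <- NULL
  csms
}

# rebuild the crosslink species encoded in an evidence/CSM row
evidence_species <- function(row, registry = built_in_modifications()) {
  alpha <- decode_peptidoform(row$alpha_peptide, row$alpha_mods,
                              registry = registry)
  beta <- decode_peptidoform(row$beta_peptide, row$beta_mods,
                             registry = registry)
  crosslink_species(alpha, beta, row$donor_site, row$acceptor_site,
                    registry[[if (row$chemistry == "C") "XL[C]" else "XL[ST]"]])
}

#' Convert identified PSMs / CSMs to site-evidence rows
#'
#' Expands the modification strings of identified PSMs (and the donor
#' sites of crosslink matches) into one row per modified-site observation,
#' the input of [call_sites()].  Fixed alkylations are not site evidence
#' and are skipped; DHAA losses map to `direct`, conjugate modifications
#' to their nucleophile, crosslinks to `XL`.
#'
#' @param psms PSM data.frame (`PSM_COLUMNS`), or `NULL`.
#' @param csms CSM data.frame (`CSM_COLUMNS`), or `NULL`.
#' @return data.frame with `accession`, `protein_pos`, `residue`,
#'   `evidence_form`, `specimen_id`.
#' @export
site_evidence <- function(psms = NULL, csms = NULL) {
  rows <- list()
  form_of <- function(name) {
    if (startsWith(name, "DHAA[")) return("direct")
    for (cj in c("GSH", "HC", "DTT", "TCEP"))
      if (startsWith(name, paste0(cj, "-DHAA"))) return(cj)
    if (startsWith(name, "XLmod:")) return("XL")
    NA_character_
  }
  if (!is.null(psms) && nrow(psms)) {
    for (i in seq_len(nrow(psms))) {
      if (!nzchar(psms$mods[i])) next
      for (tok in strsplit(psms$mods[i], ",", fixed = TRUE)[[1]]) {
        kv <- strsplit(tok, ":", fixed = TRUE)[[1]]
        form <- form_of(paste(kv[-1], collapse = ":"))
        if (is.na(form)) next
        pos <- as.integer(kv[1])
        rows[[length(rows) + 1L]] <- data.frame(
          accession = psms$accession[i],
          protein_pos = psms$start[i] + pos - 1L,
          residue = substr(psms$peptide[i], pos, pos),
          evidence_form = form, specimen_id = psms$specimen_id[i])
      }
    }
  }
  if (!is.null(csms) && nrow(csms)) {
    for (i in seq_len(nrow(csms))) {
      rows[[length(rows) + 1L]] <- data.frame(
        accession = csms$alpha_accession[i],
        protein_pos = csms$alpha_protein_site[i],
        residue = substr(csms$alpha_peptide[i], csms$donor_site[i],
                         csms$donor_site[i]),
        evidence_form = "XL", specimen_id = csms$run_id[i])
    }
  }
  if (length(rows) == 0)
    return(data.frame(accession = character(), protein_pos = integer(),
                      residue = character(), evidence_form = character(),
                      specimen_id = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
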