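#' Crosslink-spectrum search
#'
#' Searches spectra for dehydroamino-acid-mediated crosslinks against a
#' targeted protein database.  A peptide-mass index is built over the
#' tryptic digest (targets plus reversed decoys); for each spectrum every
#' (alpha, beta) pair is enumerated whose masses satisfy
#' `mass(alpha) + mass(beta) + crosslinker delta = precursor` within the
#' precursor tolerance, with alpha containing a donor residue of the
#' requested chemistry and beta an acceptor residue.  A linking cysteine
#' cannot carry its fixed alkylation, so link-form masses are computed
#' with the alkylation stripped from the linked residue.  Pairs are scored
#' on the union of both chains' crosslink fragments, the link is localized
#' to the site pair maximizing the fragment score (ties resolve to the
#' lowest positions and are flagged ambiguous), and q-values come from
#' target-decoy competition.  Heavy searches add the fixed double 18-O
#' C-terminal label to every peptide, so a crosslinked pair shifts by
#' ~8 Da relative to the light search.
#'
#' @param spectra List of [spectrum_record()] objects.
#' @param proteins Targeted protein database; keep it small (hundreds of
#'   proteins at most) — crosslink search space grows quadratically.
#' @param donor_chemistry `"ST"` (dehydroalanine/dehydrobutyrine from S/T,
#'   crosslinker delta -H2O) or `"C"` (from cysteine, delta -H2S).
#' @param acceptors Acceptor residues (default C, K, H).
#' @param params A [search_params()].
#' @param min_chain_ions Minimum matched fragment ions required on *each*
#'   chain for a CSM to be reported (default 2).  Matches supported by
#'   only one peptide are the classic crosslink false-positive mode and
#'   are discarded before FDR estimation.
#' @param keep_decoys Keep decoy and unfiltered matches; default `FALSE`.
#' @return data.frame of CSMs in the `CSM_COLUMNS` layout plus an
#'   `ambiguous` localization flag.
#' @export
search_crosslinks <- function(spectra, proteins,
                              donor_chemistry = c("ST", "C"),
                              acceptors = c("C", "K", "H"),
                              params = search_params(),
                              min_chain_ions = 2L,
                              keep_decoys = FALSE) {
  donor_chemistry <- match.arg(donor_chemistry)
  donors <- if (donor_chemistry == "ST") c("S", "T") else "C"
  xl_mod <- built_in_modifications()[[
    if (donor_chemistry == "ST") "XL[ST]" else "XL[C]"]]
  delta <- xl_mod$delta_mass
  index <- build_candidate_index(proteins,
    search_params(precursor_tol_ppm = params$precursor_tol_ppm,
                  fragment_tol_ppm = params$fragment_tol_ppm,
                  fragment_charges = params$fragment_charges,
                  fixed_mods = params$fixed_mods, variable_mods = list(),
                  digest = params$digest, label_state = params$label_state))
  cands <- index$candidates
  meta <- index$meta

  # a peptidoform with any site modification removed from the linked site
  strip_site_mod <- function(pf, pos) {
    mods <- pf$site_mods
    mods[[as.character(pos)]] <- NULL
    peptidoform(pf$sequence, mods, pf$c_term_heavy_O)
  }
  # mass contribution of a fixed mod sitting on the link site, if any
  strip_delta <- function(pf, pos) {
    m <- pf$site_mods[[as.character(pos)]]
    if (is.null(m)) 0 else m$delta_mass
  }
  # link-form entries: one row per (candidate, linkable residue class),
  # with the mass the chain contributes when linked through that class
  link_entries <- function(residue_set) {
    rows <- list()
    for (i in seq_along(cands)) {
      pf <- cands[[i]]
      for (rclass in intersect(unique(pf$residues), residue_set)) {
        site1 <- which(pf$residues == rclass)[1]
        rows[[length(rows) + 1L]] <- data.frame(
          idx = i, rclass = rclass,
          link_mass = meta$mass[i] - strip_delta(pf, site1))
      }
    }
    ent <- do.call(rbind, rows)
    if (is.null(ent))
      return(data.frame(idx = integer(), rclass = character(),
                        link_mass = numeric()))
    ent[order(ent$link_mass), , drop = FALSE]
  }
  alpha_ent <- link_entries(donors)
  beta_ent <- link_entries(acceptors)
  if (nrow(alpha_ent) == 0 || nrow(beta_ent) == 0)
    stop("targeted database contains no donor- or acceptor-bearing peptides")

  make_species <- function(ai, asite, bi, bsite) {
    crosslink_species(strip_site_mod(cands[[ai]], asite),
                      strip_site_mod(cands[[bi]], bsite),
                      asite, bsite, xl_mod)
  }
  score_pair <- function(sp, ai, asite, bi, bsite) {
    xl <- make_species(ai, asite, bi, bsite)
    score_match(sp, crosslink_fragments(xl, params$fragment_charges),
                params$fragment_tol_ppm)
  }

  rows <- list()
  for (sp in spectra) {
    neutral <- mass_from_mz(sp$precursor_mz, sp$precursor_z)
    tol_abs <- neutral * params$precursor_tol_ppm * 1e-6
    target_sum <- neutral - delta
    best <- NULL
    for (ia in seq_len(nrow(alpha_ent))) {
      need <- target_sum - alpha_ent$link_mass[ia]
      lo <- findInterval(need - tol_abs, beta_ent$link_mass) + 1L
      hi <- findInterval(need + tol_abs, beta_ent$link_mass)
      if (hi < lo) next
      ai <- alpha_ent$idx[ia]
      asite <- which(cands[[ai]]$residues == alpha_ent$rclass[ia])[1]
      for (ib in lo:hi) {
        bi <- beta_ent$idx[ib]
        bsite <- which(cands[[bi]]$residues == beta_ent$rclass[ib])[1]
        sc <- score_pair(sp, ai, asite, bi, bsite)
        dec <- meta$is_decoy[ai] || meta$is_decoy[bi]
        if (is.null(best) || sc$score > best$sc$score ||
            (sc$score == best$sc$score && best$decoy && !dec)) {
          best <- list(ai = ai, bi = bi, aclass = alpha_ent$rclass[ia],
                       bclass = beta_ent$rclass[ib], sc = sc, decoy = dec)
        }
      }
    }
    if (is.null(best) || best$sc$matched_ion_count == 0) next
    # localize the link within the best pair over same-class sites
    pa <- cands[[best$ai]]; pb <- cands[[best$bi]]
    # alternative sites must leave the species mass unchanged: same
    # residue-class group (identical stripped fixed-mod delta)
    ref_strip <- strip_delta(pb, which(pb$residues == best$bclass)[1])
    dsites <- which(pa$residues %in% donors)
    asites <- which(pb$residues %in% acceptors &
                    vapply(seq_along(pb$residues), strip_delta,
                           numeric(1), pf = pb) == ref_strip)
    loc <- expand.grid(d = dsites, acc = asites)
    loc$score <- vapply(seq_len(nrow(loc)), function(i)
      score_pair(sp, best$ai, loc$d[i], best$bi, loc$acc[i])$score,
      numeric(1))
    top <- max(loc$score)
    winners <- loc[loc$score == top, , drop = FALSE]
    winners <- winners[order(winners$d, winners$acc), , drop = FALSE]
    ambiguous <- nrow(winners) > 1
    d <- winners$d[1]; acc <- winners$acc[1]
    xl <- make_species(best$ai, d, best$bi, acc)
    # both chains must be covered by fragment evidence
    fr <- crosslink_fragments(xl, params$fragment_charges)
    n_a <- score_match(sp, fr[fr$chain == "A", ],
                       params$fragment_tol_ppm)$matched_ion_count
    n_b <- score_match(sp, fr[fr$chain == "B", ],
                       params$fragment_tol_ppm)$matched_ion_count
    if (n_a < min_chain_ions || n_b < min_chain_ions) next
    acc_a <- sub("^DECOY_", "", meta$accession[best$ai])
    acc_b <- sub("^DECOY_", "", meta$accession[best$bi])
    rows[[length(rows) + 1L]] <- data.frame(
      spectrum_id = sp$spectrum_id, run_id = sp$run_id,
      label_state = sp$label_state,
      alpha_peptide = pa$sequence, alpha_mods = encode_mods(xl$alpha),
      alpha_accession = acc_a,
      alpha_protein_site = meta$start[best$ai] + d - 1L,
      beta_peptide = pb$sequence, beta_mods = encode_mods(xl$beta),
      beta_accession = acc_b,
      beta_protein_site = meta$start[best$bi] + acc - 1L,
      donor_site = d, acceptor_site = acc, chemistry = donor_chemistry,
      precursor_mass = neutral, rt = sp$rt,
      score = top, q_value = NA_real_,
      mass_error_ppm = ppm_error(neutral, monoisotopic_mass(xl)),
      link_class = classify_link(acc_a, acc_b),
      ambiguous = ambiguous, is_decoy = best$decoy)
  }
  if (length(rows) == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = length(CSM_COLUMNS) + 1,
                             dimnames = list(NULL, c(CSM_COLUMNS, "ambiguous"))))
    return(out)
  }
  csms <- do.call(rbind, rows)
  csms$q_value <- if (any(!csms$is_decoy))
    estimate_fdr(csms$score, csms$is_decoy) else rep(1, nrow(csms))
  if (!keep_decoys) {
    csms <- csms[!csms$is_decoy & csms$q_value <= params$fdr_threshold, ]
    csms$is_decoy <- NULL
    csms <- csms[, c(CSM_COLUMNS, "ambiguous")]
  }
  rownames(csms) <- NULL
  csms
}
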