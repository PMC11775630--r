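#' Heavy/light crosslink pairing parameters
#' @param rt_window Maximum retention-time difference between the light
#'   and heavy observations, minutes (default 5).
#' @param mass_tol_ppm Mass tolerance for the +8 Da pairing and the MS1
#'   mass check, ppm (default 10).
#' @param isotope_similarity_min Minimum normalized-dot-product similarity
#'   between observed and theoretical MS1 isotope patterns (default 0.95).
#' @param full_proteome_q_max Maximum q-value allowed in the full-proteome
#'   re-search (default 0.01, the 1 percent FDR criterion).
#' @return An object of class `"pairing_params"`.
#' @export
pairing_params <- function(rt_window = 5, mass_tol_ppm = 10,
                           isotope_similarity_min = 0.95,
                           full_proteome_q_max = 0.01) {
  stopifnot(rt_window > 0, mass_tol_ppm > 0, isotope_similarity_min > 0,
            full_proteome_q_max > 0)
  structure(list(rt_window = rt_window, mass_tol_ppm = mass_tol_ppm,
                 isotope_similarity_min = isotope_similarity_min,
                 full_proteome_q_max = full_proteome_q_max),
            class = "pairing_params")
}

xl_pair_key <- function(csms) {
  paste(csms$alpha_accession, csms$alpha_protein_site,
        csms$beta_accession, csms$beta_protein_site,
        csms$alpha_peptide, csms$beta_peptide, sep = "|")
}

#' Pair light and heavy crosslink identifications
#'
#' A crosslink identified in the standard (light) digestion is paired with
#' a heavy (H2-18-O digestion) identification when the peptide pair and
#' linked sites are identical, the heavy-light neutral mass difference
#' equals the double C-terminal label for two peptides (+8.016980 Da)
#' within tolerance, and the retention times agree within the window.  A
#' +4 Da difference is the linear-peptide signature and is rejected.
#'
#' @param csms_light,csms_heavy CSM data.frames (see `CSM_COLUMNS`).
#' @param params A [pairing_params()].
#' @return data.frame of light CSMs with added columns `heavy_spectrum_id`,
#'   `heavy_mass`, `pair_delta_mass`, `pair_delta_rt`, `has_heavy_partner`.
#' @export
pair_heavy_light <- function(csms_light, csms_heavy,
                             params = pairing_params()) {
  expected <- label_18O_shift(2)
  out <- csms_light
  out$heavy_spectrum_id <- NA_character_
  out$heavy_mass <- NA_real_
  out$pair_delta_mass <- NA_real_
  out$pair_delta_rt <- NA_real_
  out$has_heavy_partner <- FALSE
  if (nrow(csms_light) == 0 || is.null(csms_heavy) || nrow(csms_heavy) == 0)
    return(out)
  lk <- xl_pair_key(csms_light)
  hk <- xl_pair_key(csms_heavy)
  for (i in seq_len(nrow(csms_light))) {
    cand <- which(hk == lk[i])
    if (length(cand) == 0) next
    dmass <- csms_heavy$precursor_mass[cand] - csms_light$precursor_mass[i]
    drt <- abs(csms_heavy$rt[cand] - csms_light$rt[i])
    tol <- csms_light$precursor_mass[i] * params$mass_tol_ppm * 1e-6
    ok <- abs(dmass - expected) <= tol & drt <= params$rt_window
    if (!any(ok)) next
    j <- cand[ok][which.min(drt[ok])]
    out$heavy_spectrum_id[i] <- csms_heavy$spectrum_id[j]
    out$heavy_mass[i] <- csms_heavy$precursor_mass[j]
    out$pair_delta_mass[i] <- csms_heavy$precursor_mass[j] -
      csms_light$precursor_mass[i]
    out$pair_delta_rt[i] <- abs(csms_heavy$rt[j] - csms_light$rt[i])
    out$has_heavy_partner[i] <- TRUE
  }
  out
}

#' Similarity between an observed and a theoretical isotope pattern
#'
#' Normalized dot product (cosine similarity) over peaks aligned within a
#' ppm tolerance; theoretical peaks with no observed counterpart
#' contribute zero.
#'
#' @param observed Two-column matrix-like of observed MS1 peaks
#'   (`mz`, `intensity`).
#' @param theory An [isotope_pattern()] (normalized intensities).
#' @param mass_tol_ppm Alignment tolerance, ppm (default 10).
#' @return Similarity in `[0, 1]`.
#' @export
isotope_similarity <- function(observed, theory, mass_tol_ppm = 10) {
  stopifnot(inherits(theory, "isotope_pattern"))
  tp <- theory$peaks
  tmz <- if ("mz" %in% names(tp)) tp$mz else tp$mass
  if (length(tmz) == 0) stop("empty theoretical pattern")
  observed <- as.matrix(observed)
  if (nrow(observed) == 0) return(0)
  omz <- observed[, 1]; oint <- observed[, 2]
  matched <- vapply(tmz, function(m) {
    tol <- m * mass_tol_ppm * 1e-6
    hit <- which(abs(omz - m) <= tol)
    if (length(hit) == 0) 0 else max(oint[hit])
  }, numeric(1))
  denom <- sqrt(sum(matched^2)) * sqrt(sum(tp$intensity^2))
  if (denom == 0) return(0)
  sum(matched * tp$intensity) / denom
}

#' Apply the three-criterion crosslink acceptance rule
#'
#' A crosslink is accepted only if (1) it has a heavy partner from
#' [pair_heavy_light()] (the 18-O +8 Da validation), (2) its precursor
#' mass matches the theoretical species mass within tolerance *and* its
#' observed MS1 isotope pattern matches the theoretical distribution, and
#' (3) both its light and heavy forms fall at or below the q-value cut in
#' a re-search against the full proteome.  Acceptance is monotone:
#' tightening any parameter never accepts a previously rejected link.
#'
#' @param evidence data.frame as produced by [pair_heavy_light()] with
#'   added columns `ms1_similarity`, `ms1_mass_error_ppm`,
#'   `full_proteome_q_light`, `full_proteome_q_heavy`.
#' @param params A [pairing_params()].
#' @return `evidence` with logical columns `crit_heavy_pair`, `crit_ms1`,
#'   `crit_full_proteome_fdr` and `accepted`.
#' @export
accept_crosslinks <- function(evidence, params = pairing_params()) {
  ev <- evidence
  ev$crit_heavy_pair <- isTRUE_vec(ev$has_heavy_partner)
  ev$crit_ms1 <- !is.na(ev$ms1_similarity) & !is.na(ev$ms1_mass_error_ppm) &
    abs(ev$ms1_mass_error_ppm) <= params$mass_tol_ppm &
    ev$ms1_similarity >= params$isotope_similarity_min
  ev$crit_full_proteome_fdr <-
    !is.na(ev$full_proteome_q_light) & !is.na(ev$full_proteome_q_heavy) &
    ev$full_proteome_q_light <= params$full_proteome_q_max &
    ev$full_proteome_q_heavy <= params$full_proteome_q_max
  ev$accepted <- ev$crit_heavy_pair & ev$crit_ms1 & ev$crit_full_proteome_fdr
  ev
}

isTRUE_vec <- function(x) !is.na(x) & x
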