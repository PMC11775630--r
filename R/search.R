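#' Search parameters
#'
#' @param precursor_tol_ppm Precursor mass tolerance, ppm (default 10).
#' @param fragment_tol_ppm Fragment m/z tolerance, ppm (default 20).
#' @param fragment_charges Fragment charges generated for scoring
#'   (default 1:2).
#' @param fdr_threshold Target-decoy q-value cut (default 0.01).
#' @param fixed_mods Named list of fixed [modification()]s applied to every
#'   eligible residue (default carbamidomethyl cysteine).
#' @param variable_mods Named list of variable modifications; candidates
#'   carry at most one variable modification.
#' @param digest A [digest_params()].
#' @param label_state `"light"` or `"heavy"`; heavy searches add the fixed
#'   double 18-O C-terminal label to every candidate.
#' @return An object of class `"search_params"`.
#' @export
search_params <- function(precursor_tol_ppm = 10, fragment_tol_ppm = 20,
                          fragment_charges = 1:2, fdr_threshold = 0.01,
                          fixed_mods = built_in_modifications()["Carbamidomethyl"],
                          variable_mods = list(),
                          digest = digest_params(),
                          label_state = c("light", "heavy")) {
  stopifnot(precursor_tol_ppm > 0, fragment_tol_ppm > 0,
            fdr_threshold > 0, fdr_threshold <= 1)
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_ppm = fragment_tol_ppm,
                 fragment_charges = as.integer(fragment_charges),
                 fdr_threshold = fdr_threshold,
                 fixed_mods = fixed_mods, variable_mods = variable_mods,
                 digest = digest, label_state = match.arg(label_state)),
            class = "search_params")
}

#' Greedy fragment matching score
#'
#' Matches theoretical ions to observed peaks within a ppm tolerance; each
#' observed peak may explain at most one theoretical ion.  The score is
#' `matched_ion_count + fraction_intensity_explained`, so ion count
#' dominates and explained intensity breaks ties.  The result is invariant
#' to the order of peaks in the spectrum.
#'
#' @param spectrum A [spectrum_record()].
#' @param theoretical data.frame with an `mz` column (e.g. from
#'   [theoretical_fragments()]), or a numeric m/z vector.
#' @param fragment_tol_ppm Match tolerance, ppm.
#' @return List with `matched_ion_count`, `fraction_intensity_explained`,
#'   `score`.
#' @export
score_match <- function(spectrum, theoretical, fragment_tol_ppm = 20) {
  theo <- if (is.data.frame(theoretical)) theoretical$mz else theoretical
  obs <- spectrum$fragments
  if (nrow(obs) == 0 || length(theo) == 0)
    return(list(matched_ion_count = 0L, fraction_intensity_explained = 0,
                score = 0))
  theo <- sort(theo)
  used <- rep(FALSE, nrow(obs))
  matched <- 0L
  explained <- 0
  omz <- obs[, "mz"]
  for (t in theo) {
    tol <- t * fragment_tol_ppm * 1e-6
    lo <- findInterval(t - tol, omz) + 1L
    hi <- findInterval(t + tol, omz)
    if (hi < lo) next
    cand <- lo:hi
    cand <- cand[!used[cand]]
    if (length(cand) == 0) next
    best <- cand[which.min(abs(omz[cand] - t))]
    used[best] <- TRUE
    matched <- matched + 1L
    explained <- explained + obs[best, "intensity"]
  }
  total <- sum(obs[, "intensity"])
  frac <- if (total > 0) as.numeric(explained / total) else 0
  list(matched_ion_count = matched, fraction_intensity_explained = frac,
       score = as.numeric(matched + frac))
}

#' Target-decoy q-value estimation
#'
#' Standard target-decoy FDR: at score threshold `s`,
#' `FDR(s) = #decoys >= s / #targets >= s`, capped at 1 and monotonized so
#' that q never decreases as the score threshold is lowered.
#'
#' @param score Numeric match scores.
#' @param is_decoy Logical decoy flags, same length.
#' @return Numeric q-values, one per input match.
#' @export
estimate_fdr <- function(score, is_decoy) {
  stopifnot(length(score) == length(is_decoy))
  if (sum(!is_decoy) == 0) stop("no target matches")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; d <- is_decoy[ord]
  cum_d <- cumsum(d)
  cum_t <- cumsum(!d)
  # ties share the counts accumulated at the last element of the tie group
  last_idx <- length(s) + 1L - match(s, rev(s))
  D <- cum_d[last_idx]
  Tn <- cum_t[last_idx]
  fdr <- ifelse(Tn == 0, 1, pmin(1, D / Tn))
  q <- rev(cummin(rev(fdr)))  # monotone: q(high score) <= q(low score)
  out <- numeric(length(score))
  out[ord] <- q
  out
}

# Build the candidate peptidoform index for a linear search: tryptic
# digest of targets plus reversed decoys (C-terminal residue kept in
# place, preserving the tryptic mass distribution), fixed modifications
# applied everywhere, at most one variable modification per candidate.
# Returns a list(candidates = list of peptidoform, meta = data.frame).
build_candidate_index <- function(proteins, params) {
  if (nrow(proteins) == 0) stop("empty protein database")
  decoys <- proteins
  decoys$accession <- paste0("DECOY_", decoys$accession)
  decoys$sequence <- vapply(proteins$sequence, function(s) {
    n <- nchar(s)
    if (n < 2) return(s)
    paste0(paste(rev(strsplit(substr(s, 1, n - 1), "")[[1]]), collapse = ""),
           substr(s, n, n))
  }, character(1), USE.NAMES = FALSE)
  all_prot <- rbind(proteins[, c("accession", "sequence")],
                    decoys[, c("accession", "sequence")])
  digest <- digest_proteome(all_prot, params$digest)
  digest <- digest[!duplicated(digest[, c("accession", "peptide", "start")]), ]
  heavy <- if (params$label_state == "heavy") 2L else 0L

  cands <- list(); meta <- list()
  add <- function(pf, acc, start, is_decoy, varmod, varpos) {
    k <- length(cands) + 1L
    cands[[k]] <<- pf
    meta[[k]] <<- data.frame(accession = acc, start = start,
                             is_decoy = is_decoy, varmod = varmod,
                             varpos = varpos, mass = monoisotopic_mass(pf))
  }
  for (i in seq_len(nrow(digest))) {
    pep <- digest$peptide[i]
    res <- strsplit(pep, "")[[1]]
    fixed <- list()
    for (fm in params$fixed_mods)
      for (pos in which(res %in% fm$targets))
        fixed[[as.character(pos)]] <- fm
    is_dec <- startsWith(digest$accession[i], "DECOY_")
    base <- peptidoform(pep, fixed, heavy)
    add(base, digest$accession[i], digest$start[i], is_dec, "", NA_integer_)
    for (vm in params$variable_mods) {
      # a variable modification displaces any fixed alkylation at its
      # site: an eliminylated or conjugated cysteine cannot also carry
      # carbamidomethyl
      open_pos <- which(res %in% vm$targets)
      if (!is.null(vm$site_specific)) {
        # site-specific custom modifications (appended crosslinks) apply
        # only at their observed protein coordinate
        open_pos <- open_pos[
          digest$accession[i] == vm$site_specific$accession &
          digest$start[i] + open_pos - 1L == vm$site_specific$protein_pos]
      }
      for (pos in open_pos) {
        mods <- fixed
        mods[[as.character(pos)]] <- vm
        add(peptidoform(pep, mods, heavy), digest$accession[i],
            digest$start[i], is_dec, vm$name, pos)
      }
    }
  }
  meta <- do.call(rbind, meta)
  ord <- order(meta$mass)
  list(candidates = cands[ord], meta = meta[ord, , drop = FALSE])
}

# indices of candidate masses within ppm tolerance of a neutral mass
mass_window <- function(masses, target, tol_ppm) {
  tol <- target * tol_ppm * 1e-6
  lo <- findInterval(target - tol, masses) + 1L
  hi <- findInterval(target + tol, masses)
  if (hi < lo) integer(0) else lo:hi
}

#' Linear peptide-spectrum search with target-decoy FDR
#'
#' For each spectrum, scores every candidate peptidoform (target or
#' reversed decoy) whose mass lies within the precursor tolerance, keeps
#' the best match, estimates q-values by target-decoy competition, and
#' returns target PSMs filtered at the configured FDR threshold.
#'
#' @param spectra List of [spectrum_record()] objects.
#' @param proteins Protein database (data.frame as from [read_fasta()]).
#' @param params A [search_params()].
#' @param keep_decoys Keep decoy matches and unfiltered results (for
#'   diagnostics); default `FALSE`.
#' @return data.frame of PSMs in the `PSM_COLUMNS` layout.
#' @export
search_linear <- function(spectra, proteins, params = search_params(),
                          keep_decoys = FALSE) {
  index <- build_candidate_index(proteins, params)
  masses <- index$meta$mass
  rows <- list()
  for (sp in spectra) {
    neutral <- mass_from_mz(sp$precursor_mz, sp$precursor_z)
    hits <- mass_window(masses, neutral, params$precursor_tol_ppm)
    if (length(hits) == 0) next
    best <- NULL
    for (h in hits) {
      sc <- score_match(sp,
                        theoretical_fragments(index$candidates[[h]],
                                              params$fragment_charges),
                        params$fragment_tol_ppm)
      # ties: prefer target over decoy, then lower candidate index
      if (is.null(best) || sc$score > best$sc$score ||
          (sc$score == best$sc$score && best$meta$is_decoy &&
           !index$meta$is_decoy[h])) {
        best <- list(h = h, sc = sc, meta = index$meta[h, ])
      }
    }
    pf <- index$candidates[[best$h]]
    rows[[length(rows) + 1L]] <- data.frame(
      spectrum_id = sp$spectrum_id, run_id = sp$run_id,
      specimen_id = sp$run_id, group = NA_character_,
      accession = best$meta$accession, start = best$meta$start,
      peptide = pf$sequence, mods = encode_mods(pf),
      c_term_heavy_O = pf$c_term_heavy_O,
      score = best$sc$score, q_value = NA_real_,
      mass_error_ppm = ppm_error(neutral, best$meta$mass),
      intensity = sp$precursor_intensity,
      is_decoy = best$meta$is_decoy)
  }
  if (length(rows) == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = length(PSM_COLUMNS),
                             dimnames = list(NULL, PSM_COLUMNS)))
    return(out)
  }
  psms <- do.call(rbind, rows)
  psms$q_value <- if (any(!psms$is_decoy))
    estimate_fdr(psms$score, psms$is_decoy) else rep(1, nrow(psms))
  if (!keep_decoys) {
    psms <- psms[!psms$is_decoy & psms$q_value <= params$fdr_threshold, ]
    psms$is_decoy <- NULL
    psms <- psms[, PSM_COLUMNS]
  }
  rownames(psms) <- NULL
  psms
}
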