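#' Simulation parameters
#'
#' Defaults describe the study conditions the package is benchmarked
#' under: 48 disease (AD) vs 44 control specimens, crosslink features
#' planted 10-fold more abundant in AD, log-normal intensity noise
#' (sigma 0.3 on the log scale), 2 ppm mass error, and 95 percent
#' isotopic purity of the heavy digestion water.
#'
#' @param seed Integer seed; fixes all downstream randomness.
#' @param n_proteins Number of simulated proteins.
#' @param segments_per_protein Tryptic segments per protein (each segment
#'   ends in K/R, giving digestible sequences).
#' @param n_specimens_AD,n_specimens_CTR Group sizes for the intensity
#'   matrix (defaults 48 and 44).
#' @param n_direct_sites Planted direct-loss (unconjugated DHAA) sites.
#' @param n_conjugate_sites Named integer vector of planted conjugate
#'   sites per kind (GSH/HC/DTT/TCEP).
#' @param n_crosslinks_intra,n_crosslinks_inter Planted crosslinks within
#'   one protein / between proteins.
#' @param n_crosslinks_light_only Planted crosslinks simulated only in the
#'   light runs (negative controls for the 18-O validation).
#' @param ppm_error_sd Gaussian precursor/fragment mass error, ppm.
#' @param rt_jitter_sd Retention-time jitter between paired runs, minutes.
#' @param sigma_log Log-normal intensity noise (sd of log intensities).
#' @param fold_change_xl Planted AD/CTR fold change for crosslink features.
#' @param heavy_exchange_fraction Probability a heavy-run species is fully
#'   18-O exchanged (95 percent isotopic purity); otherwise one oxygen
#'   remains light.
#' @param n_noise_peaks Uniform-random noise peaks per MS2 spectrum.
#' @param n_runs Paired light/heavy runs (fractions) per simulated study;
#'   two by default, so that occasional partial 18-O exchange in one run
#'   does not erase a species from the heavy condition.
#' @param embed_fixtures Embed the synthetic-standard peptides
#'   (`IGSTENLK`, `SPVVSGDTSPR`, `CGSKDNIK`) as tryptic windows.
#' @return An object of class `"simulation_params"`.
#' @export
simulation_params <- function(seed = 1L, n_proteins = 30L,
                              segments_per_protein = 12L,
                              n_specimens_AD = 48L, n_specimens_CTR = 44L,
                              n_direct_sites = 10L,
                              n_conjugate_sites = c(GSH = 6, HC = 4,
                                                    DTT = 3, TCEP = 3),
                              n_crosslinks_intra = 6L,
                              n_crosslinks_inter = 6L,
                              n_crosslinks_light_only = 3L,
                              ppm_error_sd = 2, rt_jitter_sd = 0.5,
                              sigma_log = 0.3, fold_change_xl = 10,
                              heavy_exchange_fraction = 0.95,
                              n_noise_peaks = 30L, n_runs = 2L,
                              embed_fixtures = FALSE) {
  stopifnot(n_proteins > 0, segments_per_protein > 0,
            heavy_exchange_fraction >= 0, heavy_exchange_fraction <= 1,
            ppm_error_sd >= 0, sigma_log >= 0)
  structure(as.list(environment()), class = "simulation_params")
}

# residue alphabet for simulated segment interiors: excludes K/R (segment
# terminators) and P (to avoid cleavage suppression complicating tiling)
SIM_RESIDUES <- c("A", "S", "G", "V", "T", "C", "L", "I", "N", "D", "Q",
                  "E", "M", "H", "F", "Y", "W")
SIM_WEIGHTS <- c(8, 8, 7, 6, 6, 3, 9, 5, 4, 5, 4, 6, 2, 3, 4, 3, 1)

FIXTURE_PEPTIDES <- c("IGSTENLK", "SPVVSGDTSPR", "CGSKDNIK")

#' Generate a random tryptic-friendly proteome
#'
#' Proteins are concatenations of segments of 5-14 interior residues
#' ending in K or R, so a tryptic digest yields well-behaved peptides.
#' With `embed_fixtures` the three synthetic-standard peptides are placed
#' as segments of the first proteins.  Byte-identical for a fixed seed.
#'
#' @param params A [simulation_params()].
#' @return List (`ground_truth` skeleton) with `proteins` (data.frame) and
#'   empty planting tables.
#' @export
generate_proteome <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  withr_seed(params$seed, {
    proteins <- lapply(seq_len(params$n_proteins), function(i) {
      segs <- vapply(seq_len(params$segments_per_protein), function(j) {
        len <- sample(5:14, 1)
        paste0(paste(sample(SIM_RESIDUES, len, replace = TRUE,
                            prob = SIM_WEIGHTS), collapse = ""),
               sample(c("K", "R"), 1))
      }, character(1))
      if (params$embed_fixtures && i <= length(FIXTURE_PEPTIDES))
        segs[2] <- FIXTURE_PEPTIDES[i]
      data.frame(accession = sprintf("SIMP%03d", i),
                 description = sprintf("simulated protein %d", i),
                 sequence = paste(segs, collapse = ""))
    })
    list(proteins = do.call(rbind, proteins),
         sites = NULL, crosslinks = NULL, params = params)
  })
}

# peptides eligible for planting: unique zero-missed tryptic peptides of
# length 6..25 that occur exactly once in the proteome
eligible_peptides <- function(proteins) {
  dig <- digest_proteome(proteins, digest_params(0, 6, 25))
  counts <- table(dig$peptide)
  dig[dig$peptide %in% names(counts)[counts == 1], ]
}

#' Plant DHAA sites, conjugates and crosslinks into a simulated proteome
#'
#' Sites are drawn without collision from eligible residues (S/T/C for
#' eliminylation forms, donor S/T/C plus acceptor C/K/H for crosslinks);
#' requesting more sites than eligible residues is an error.  Crosslinks
#' are split intra/inter per the parameters, and a configurable number of
#' light-only crosslinks serve as negative controls for 18-O validation.
#'
#' @param truth Skeleton from [generate_proteome()].
#' @param params A [simulation_params()].
#' @return Completed ground truth: adds `sites` (accession, protein_pos,
#'   residue, form, peptide, pep_pos, start) and `crosslinks` (donor and
#'   acceptor coordinates, chemistry, link_class, in_heavy).
#' @export
plant_modifications <- function(truth, params = truth$params) {
  proteins <- truth$proteins
  withr_seed(params$seed + 1L, {
    pep <- eligible_peptides(proteins)
    pep <- pep[order(pep$accession, pep$start), ]
    # one candidate row per (peptide occurrence, residue position)
    site_rows <- do.call(rbind, lapply(seq_len(nrow(pep)), function(i) {
      res <- strsplit(pep$peptide[i], "")[[1]]
      pos <- which(res %in% c("S", "T", "C"))
      if (!length(pos)) return(NULL)
      data.frame(accession = pep$accession[i], peptide = pep$peptide[i],
                 start = pep$start[i], pep_pos = pos, residue = res[pos],
                 protein_pos = pep$start[i] + pos - 1L)
    }))
    forms <- c(rep("direct", params$n_direct_sites),
               rep(names(params$n_conjugate_sites),
                   params$n_conjugate_sites))
    n_sites <- length(forms)
    if (n_sites > nrow(site_rows))
      stop("more planted sites requested than eligible residues")
    # at most one planted site per peptide to keep features unambiguous
    one_per_pep <- site_rows[!duplicated(site_rows$peptide), ]
    if (n_sites > nrow(one_per_pep))
      stop("more planted sites requested than eligible peptides")
    picked <- one_per_pep[sample(nrow(one_per_pep), n_sites), ]
    picked$form <- sample(forms)  # shuffle form assignment
    used_peps <- picked$peptide

    n_xl <- params$n_crosslinks_intra + params$n_crosslinks_inter +
      params$n_crosslinks_light_only
    donor_pool <- site_rows[!site_rows$peptide %in% used_peps &
                            site_rows$residue %in% c("S", "T", "C"), ]
    donor_pool <- donor_pool[!duplicated(donor_pool$peptide), ]
    acc_rows <- do.call(rbind, lapply(seq_len(nrow(pep)), function(i) {
      res <- strsplit(pep$peptide[i], "")[[1]]
      pos <- which(res %in% c("C", "K", "H"))
      # a C-terminal K cannot accept: it is the tryptic terminus
      pos <- pos[!(res[pos] == "K" & pos == length(res))]
      if (!length(pos)) return(NULL)
      data.frame(accession = pep$accession[i], peptide = pep$peptide[i],
                 start = pep$start[i], pep_pos = pos, residue = res[pos],
                 protein_pos = pep$start[i] + pos - 1L)
    }))
    xls <- list()
    want <- c(rep("intra", params$n_crosslinks_intra),
              rep("inter", params$n_crosslinks_inter),
              rep(NA, params$n_crosslinks_light_only))
    for (k in seq_len(n_xl)) {
      placed <- FALSE
      for (attempt in seq_len(500)) {
        d <- donor_pool[sample(nrow(donor_pool), 1), ]
        pool <- acc_rows[acc_rows$peptide != d$peptide &
                         !acc_rows$peptide %in% used_peps, ]
        # never link adjacent tryptic peptides: with a -H2O crosslinker
        # the species is isobaric with the missed-cleavage linear
        # peptide and cannot be resolved in the light condition
        d_end <- d$start + nchar(d$peptide) - 1L
        adjacent <- pool$accession == d$accession &
          (pool$start == d_end + 1L |
           pool$start + nchar(pool$peptide) == d$start)
        pool <- pool[!adjacent, ]
        cls <- want[k]
        if (!is.na(cls))
          pool <- pool[(pool$accession == d$accession) == (cls == "intra"), ]
        if (!nrow(pool)) next
        a <- pool[sample(nrow(pool), 1), ]
        used_peps <- c(used_peps, d$peptide, a$peptide)
        donor_pool <- donor_pool[!donor_pool$peptide %in% used_peps, ]
        if (!nrow(donor_pool) && k < n_xl)
          stop("insufficient eligible residues to plant all crosslinks")
        xls[[k]] <- data.frame(
          donor_accession = d$accession, donor_peptide = d$peptide,
          donor_start = d$start, donor_pep_pos = d$pep_pos,
          donor_residue = d$residue, donor_protein_pos = d$protein_pos,
          acceptor_accession = a$accession, acceptor_peptide = a$peptide,
          acceptor_start = a$start, acceptor_pep_pos = a$pep_pos,
          acceptor_residue = a$residue, acceptor_protein_pos = a$protein_pos,
          chemistry = if (d$residue == "C") "C" else "ST",
          link_class = classify_link(d$accession, a$accession),
          in_heavy = k <= params$n_crosslinks_intra +
            params$n_crosslinks_inter)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("insufficient eligible residues to plant all crosslinks ",
             "(no acceptor available for the requested link class)")
    }
    truth$sites <- picked[, c("accession", "protein_pos", "residue", "form",
                              "peptide", "pep_pos", "start")]
    truth$crosslinks <- do.call(rbind, xls)
    rownames(truth$sites) <- rownames(truth$crosslinks) <- NULL
    truth
  })
}

# peptidoform for a planted linear site observation
site_peptidoform <- function(site, heavy = FALSE,
                             registry = built_in_modifications()) {
  res <- strsplit(site$peptide, "")[[1]]
  mods <- list()
  cam <- registry[["Carbamidomethyl"]]
  for (p in which(res == "C")) mods[[as.character(p)]] <- cam
  modname <- if (site$form == "direct") {
    if (site$residue == "C") "DHAA[C]" else "DHAA[ST]"
  } else {
    paste0(site$form, "-DHAA[", if (site$residue == "C") "C" else "ST", "]")
  }
  mods[[as.character(site$pep_pos)]] <- registry[[modname]]
  peptidoform(site$peptide, mods, if (heavy) 2L else 0L)
}

# crosslink species for a planted crosslink
xl_species <- function(xl, heavy = FALSE,
                       registry = built_in_modifications()) {
  cam <- registry[["Carbamidomethyl"]]
  chain <- function(pepseq, link_pos) {
    res <- strsplit(pepseq, "")[[1]]
    mods <- list()
    for (p in setdiff(which(res == "C"), link_pos))
      mods[[as.character(p)]] <- cam
    peptidoform(pepseq, mods, if (heavy) 2L else 0L)
  }
  crosslink_species(chain(xl$donor_peptide, xl$donor_pep_pos),
                    chain(xl$acceptor_peptide, xl$acceptor_pep_pos),
                    xl$donor_pep_pos, xl$acceptor_pep_pos,
                    registry[[if (xl$chemistry == "C") "XL[C]" else "XL[ST]"]])
}

simulate_one_spectrum <- function(species, id, run_id, label_state, rt,
                                  params, charge, intensity) {
  is_xl <- inherits(species, "crosslink_species")
  neutral <- monoisotopic_mass(species)
  partial <- label_state == "heavy" &&
    stats::runif(1) > params$heavy_exchange_fraction
  if (partial)  # one C-terminal oxygen escaped exchange
    neutral <- neutral - (ATOMIC_MASS[["O18"]] - ATOMIC_MASS[["O"]])
  ppm <- function(n) stats::rnorm(n, 0, params$ppm_error_sd) * 1e-6
  mz <- mz_from_mass(neutral, charge) * (1 + ppm(1))
  theo <- if (is_xl) crosslink_fragments(species, 1L)
          else theoretical_fragments(species, 1L)
  fmz <- theo$mz * (1 + ppm(nrow(theo)))
  fint <- stats::runif(nrow(theo), 0.2, 1)
  base <- max(fint)
  noise_mz <- stats::runif(params$n_noise_peaks, 150, 1500)
  noise_int <- stats::runif(params$n_noise_peaks, 0.01, 0.1) * base
  frag <- cbind(mz = c(fmz, noise_mz), intensity = c(fint, noise_int))
  frag <- frag[order(frag[, 1]), , drop = FALSE]
  comp <- if (is_xl) crosslink_composition(species)
          else peptide_composition(species)
  pat <- isotope_pattern(comp, charge = charge, n_peaks = 5)
  ms1 <- cbind(mz = pat$peaks$mz * (1 + ppm(nrow(pat$peaks))),
               intensity = pat$peaks$intensity * intensity)
  if (partial)
    ms1[, "mz"] <- ms1[, "mz"] -
      (ATOMIC_MASS[["O18"]] - ATOMIC_MASS[["O"]]) / charge
  spectrum_record(id, run_id, label_state, mz, charge, rt,
                  fragments = frag, ms1_peaks = ms1,
                  precursor_intensity = intensity)
}

#' Simulate MS2 spectra (with MS1 isotope blocks) for a planted truth
#'
#' One spectrum per planted linear peptidoform and per planted crosslink.
#' Heavy runs carry the double 18-O C-terminal label on every peptide
#' (crosslinked pairs shift ~+8 Da, linear peptides ~+4 Da); with
#' probability `1 - heavy_exchange_fraction` a heavy species is only
#' partially exchanged.  Retention times are consistent between paired
#' light/heavy runs up to `rt_jitter_sd`.  Deterministic for a fixed seed
#' (per run and label state).
#'
#' @param truth Completed ground truth from [plant_modifications()].
#' @param label_state `"light"` or `"heavy"`.
#' @param run_id Run identifier (also seeds the run-specific RNG stream).
#' @param params A [simulation_params()].
#' @return List of [spectrum_record()] objects.
#' @export
simulate_spectra <- function(truth, label_state = c("light", "heavy"),
                             run_id = "run1", params = truth$params) {
  label_state <- match.arg(label_state)
  heavy <- label_state == "heavy"
  # species-level RT and intensity are seeded independently of the run so
  # paired light/heavy runs share them
  n_feat <- nrow(truth$sites) + nrow(truth$crosslinks)
  base <- withr_seed(params$seed + 2L, list(
    rt = stats::runif(n_feat, 10, 100),
    intensity = stats::rlnorm(n_feat, log(1e6), 0.5)))
  run_seed <- params$seed + 3L +
    sum(utf8ToInt(paste0(run_id, label_state))) %% 10000L
  withr_seed(run_seed, {
    spectra <- list()
    k <- 0
    for (i in seq_len(nrow(truth$sites))) {
      k <- k + 1
      s <- truth$sites[i, ]
      pf <- site_peptidoform(s, heavy)
      spectra[[k]] <- simulate_one_spectrum(
        pf, sprintf("%s_%s_site%03d", run_id, label_state, i), run_id,
        label_state, base$rt[k] + stats::rnorm(1, 0, params$rt_jitter_sd),
        params, charge = 2L, intensity = base$intensity[k])
    }
    for (i in seq_len(nrow(truth$crosslinks))) {
      k <- k + 1
      x <- truth$crosslinks[i, ]
      if (heavy && !x$in_heavy) next
      xl <- xl_species(x, heavy)
      spectra[[length(spectra) + 1L]] <- simulate_one_spectrum(
        xl, sprintf("%s_%s_xl%03d", run_id, label_state, i), run_id,
        label_state, base$rt[k] + stats::rnorm(1, 0, params$rt_jitter_sd),
        params, charge = 4L, intensity = base$intensity[k])
    }
    spectra
  })
}

#' Simulate an AD/CTR intensity matrix with planted fold changes
#'
#' Log-normal intensities per feature and specimen; crosslink features
#' carry the planted multiplicative fold change in the AD columns, site
#' features are null.  The planted-effect table is returned for recovery
#' scoring.
#'
#' @param truth Completed ground truth.
#' @param params A [simulation_params()].
#' @return List with `matrix` (features x specimens), `groups` (named
#'   specimen -> group vector) and `effects` (feature, planted_fold).
#' @export
simulate_intensity_matrix <- function(truth, params = truth$params) {
  site_feats <- sprintf("site:%s:%s%d[%s]", truth$sites$accession,
                        truth$sites$residue, truth$sites$protein_pos,
                        truth$sites$form)
  xl_feats <- sprintf("xl:%s:%s%d-%s:%s%d",
                      truth$crosslinks$donor_accession,
                      truth$crosslinks$donor_residue,
                      truth$crosslinks$donor_protein_pos,
                      truth$crosslinks$acceptor_accession,
                      truth$crosslinks$acceptor_residue,
                      truth$crosslinks$acceptor_protein_pos)
  feats <- c(site_feats, xl_feats)
  fold <- c(rep(1, length(site_feats)),
            rep(params$fold_change_xl, length(xl_feats)))
  specs <- c(sprintf("AD%02d", seq_len(params$n_specimens_AD)),
             sprintf("CTR%02d", seq_len(params$n_specimens_CTR)))
  groups <- stats::setNames(rep(c("AD", "CTR"),
                                c(params$n_specimens_AD,
                                  params$n_specimens_CTR)), specs)
  withr_seed(params$seed + 4L, {
    meanlog <- stats::rnorm(length(feats), log(1e6), 1)
    m <- matrix(NA_real_, length(feats), length(specs),
                dimnames = list(feats, specs))
    for (j in seq_along(specs)) {
      mult <- if (groups[[j]] == "AD") fold else rep(1, length(fold))
      m[, j] <- stats::rlnorm(length(feats), meanlog + log(mult),
                              params$sigma_log)
    }
    list(matrix = m, groups = groups,
         effects = data.frame(feature = feats, planted_fold = fold))
  })
}

#' Run the full simulation
#'
#' Convenience wrapper: proteome, planted modifications, paired
#' light/heavy spectra and the intensity matrix, all from one seed.
#' @param params A [simulation_params()].
#' @return List with `truth`, `spectra_light`, `spectra_heavy`,
#'   `intensities`.
#' @export
simulate_study <- function(params = simulation_params()) {
  truth <- plant_modifications(generate_proteome(params), params)
  runs <- sprintf("run%d", seq_len(params$n_runs))
  pool <- function(label) do.call(c, lapply(runs, function(r)
    simulate_spectra(truth, label, r, params)))
  list(truth = truth,
       spectra_light = pool("light"),
       spectra_heavy = pool("heavy"),
       intensities = simulate_intensity_matrix(truth, params))
}
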