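proton <- 1.00727646688

test_that("fragment counts and label arithmetic are correct", {
  p <- peptidoform("IGSTENLK")
  fr <- theoretical_fragments(p, 1L)
  expect_equal(nrow(fr), 14)  # 7 b + 7 y at one charge
  h <- peptidoform("IGSTENLK", c_term_heavy_O = 2L)
  frh <- theoretical_fragments(h, 1L)
  # all y ions shift by the label, b ions are untouched
  expect_equal(frh$mz[frh$type == "y"] - fr$mz[fr$type == "y"],
               rep(label_18O_shift(1), 7), tolerance = 1e-9)
  expect_equal(frh$mz[frh$type == "b"], fr$mz[fr$type == "b"])
  # a site mod shifts exactly the spanning ions
  mods <- built_in_modifications()
  pm <- peptidoform("IGSTENLK", list(`3` = mods[["DHAA[ST]"]]))
  frm <- theoretical_fragments(pm, 1L)
  d <- frm$mz - fr$mz
  expect_equal(d[frm$type == "b"][1:2], c(0, 0))
  expect_equal(d[frm$type == "b"][3:7], rep(eliminylation_delta("S"), 5),
               tolerance = 1e-9)
})

test_that("crosslink fragments carry the partner only across the link", {
  mods <- built_in_modifications()
  xl <- crosslink_species(peptidoform("SPVVSGDTSPR"), peptidoform("CGSKDNIK"),
                          5, 1, mods[["XL[ST]"]])
  fr <- crosslink_fragments(xl, 1L)
  expect_equal(nrow(fr), 2 * 10 + 2 * 7)  # lengths 11 and 8, one charge
  y7 <- fr[fr$chain == "A" & fr$ion == "y7", ]
  expect_true(y7$carries_crosslink)
  expect_equal(y7$mz - proton, 1563.731118, tolerance = 1e-5)
  # b4 (SPVV) does not span the site: identical to the linear fragment
  b4 <- fr[fr$chain == "A" & fr$ion == "b4", ]
  lin <- theoretical_fragments(peptidoform("SPVVSGDTSPR"), 1L)
  expect_false(b4$carries_crosslink)
  expect_equal(b4$mz, lin$mz[lin$ion == "b4"])
  # removing the partner mass and delta recovers the linear fragments
  nocarry <- fr[fr$chain == "A" & !fr$carries_crosslink, ]
  expect_equal(nocarry$mz, lin$mz[match(nocarry$ion, lin$ion)])
})

test_that("greedy scoring matches peaks once, within tolerance only", {
  p <- peptidoform("IGSTENLK")
  theo <- theoretical_fragments(p, 1L)
  sp <- spectrum_record("s", precursor_mz = mz_from_mass(monoisotopic_mass(p), 2),
                        precursor_z = 2,
                        fragments = cbind(sort(theo$mz), rep(1, nrow(theo))))
  sc <- score_match(sp, theo, 20)
  expect_equal(sc$matched_ion_count, 14L)
  expect_equal(sc$fraction_intensity_explained, 1.0)
  # empty spectrum
  empty <- spectrum_record("e", precursor_mz = 500, precursor_z = 2)
  expect_equal(score_match(empty, theo, 20)$matched_ion_count, 0L)
  # peaks shifted by 3x tolerance never match
  shifted <- spectrum_record("sh", precursor_mz = 500, precursor_z = 2,
                             fragments = cbind(sort(theo$mz) * (1 + 60e-6),
                                               rep(1, nrow(theo))))
  expect_equal(score_match(shifted, theo, 20)$matched_ion_count, 0L)
  # permutation invariance of the spectrum peak order
  set.seed(1)
  perm <- sample(nrow(theo))
  expect_warning(
    sp2 <- spectrum_record("s2", precursor_mz = 500, precursor_z = 2,
                           fragments = cbind(theo$mz[perm],
                                             runif(nrow(theo)))),
    "unsorted")
  expect_equal(score_match(sp2, theo, 20)$matched_ion_count, 14L)
})

test_that("target-decoy q-values agree with direct counting", {
  expect_equal(estimate_fdr(c(5, 4, 3), c(FALSE, FALSE, FALSE)),
               c(0, 0, 0))
  expect_equal(estimate_fdr(rep(2, 6), rep(c(TRUE, FALSE), 3)),
               rep(1, 6))
  set.seed(77)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    score <- round(rnorm(n), sample(c(1, 2), 1))  # force some ties
    dec <- runif(n) < 0.4
    if (all(dec)) dec[1] <- FALSE
    expect_equal(estimate_fdr(score, dec), brute_q(score, dec),
                 tolerance = 1e-12)
  }
  expect_error(estimate_fdr(1:3, rep(TRUE, 3)), "no target")
})

test_that("linear search recovers noiseless planted peptides at q = 0", {
  prots <- data.frame(
    accession = c("T1", "T2"), description = "",
    sequence = c("MKSAGELLDKAVTSLIEKGGSSEEDLLR", "AKQPLEDNIRGTENWFK"))
  par <- search_params(fixed_mods = list())
  idx <- dhaaxl:::build_candidate_index(prots, par)
  keep <- !idx$meta$is_decoy
  pfs <- idx$candidates[keep][1:8]
  spectra <- lapply(seq_along(pfs), function(i) {
    theo <- theoretical_fragments(pfs[[i]], 1:2)
    spectrum_record(paste0("sp", i),
                    precursor_mz = mz_from_mass(monoisotopic_mass(pfs[[i]]), 2),
                    precursor_z = 2,
                    fragments = cbind(sort(theo$mz), rep(1, nrow(theo))))
  })
  psms <- search_linear(spectra, prots, par)
  expect_equal(nrow(psms), 8)
  expect_true(all(psms$q_value == 0))
  expect_setequal(psms$peptide,
                  vapply(pfs, `[[`, character(1), "sequence"))
  # spectrum with no candidate in tolerance yields no PSM
  stray <- spectrum_record("x", precursor_mz = 333.333, precursor_z = 2,
                           fragments = cbind(500, 1))
  expect_equal(nrow(search_linear(list(stray), prots, par)), 0)
  expect_error(search_linear(spectra, prots[0, ], par), "empty")
})

test_that("delta-mass discovery finds and localizes planted conjugates", {
  mods <- built_in_modifications()
  prots <- data.frame(accession = "P1", description = "",
                      sequence = "MKAVTSLIEKGGSAEEDLLRAGELFDK")
  # plant GSH-DHAA on the S of AVTSLIEK (protein position 6)
  pf <- peptidoform("AVTSLIEK", list(`4` = mods[["GSH-DHAA[ST]"]]))
  theo <- theoretical_fragments(pf, 1:2)
  sp <- spectrum_record("g1",
                        precursor_mz = mz_from_mass(monoisotopic_mass(pf), 2),
                        precursor_z = 2,
                        fragments = cbind(sort(theo$mz), rep(1, nrow(theo))))
  cands <- mods[c("DHAA[ST]", "DHAA[C]", "GSH-DHAA[ST]", "HC-DHAA[ST]")]
  hits <- discover_delta_mods(list(sp), prots,  cands,
                              search_params(fixed_mods = list()))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mod_name, "GSH-DHAA[ST]")
  expect_equal(hits$peptide, "AVTSLIEK")
  # fragments discriminate T3 from S4: localization must pick position 4
  expect_equal(hits$peptide_pos, 4L)
  expect_equal(hits$protein_pos, 6L)
  # delta 0 (unmodified peptide) discovers nothing
  pf0 <- peptidoform("AVTSLIEK")
  theo0 <- theoretical_fragments(pf0, 1:2)
  sp0 <- spectrum_record("g0",
                         precursor_mz = mz_from_mass(monoisotopic_mass(pf0), 2),
                         precursor_z = 2,
                         fragments = cbind(sort(theo0$mz), rep(1, nrow(theo0))))
  expect_equal(nrow(discover_delta_mods(list(sp0), prots, cands,
                                        search_params(fixed_mods = list()))),
               0)
})

test_that("crosslink search recovers planted links; wrong chemistry finds none", {
  sim <- small_sim()
  tr <- sim$truth$crosslinks
  par <- search_params()
  csms_st <- search_crosslinks(sim$spectra_light, sim$truth$proteins, "ST",
                               params = par)
  csms_c <- search_crosslinks(sim$spectra_light, sim$truth$proteins, "C",
                              params = par)
  csms <- rbind(csms_st, csms_c)
  key_t <- xl_key(tr$donor_accession, tr$donor_protein_pos,
                  tr$acceptor_accession, tr$acceptor_protein_pos)
  key_e <- xl_key(csms$alpha_accession, csms$alpha_protein_site,
                  csms$beta_accession, csms$beta_protein_site)
  found <- key_t %in% key_e[csms$q_value <= 0.01]
  expect_gte(mean(found), 0.9)
  # searching ST-planted spectra with the C-derived delta recovers none
  st_spectra_ids <- paste0("run1_light_xl",
                           sprintf("%03d", which(tr$chemistry == "ST")))
  st_spectra <- Filter(function(s) s$spectrum_id %in% st_spectra_ids,
                       sim$spectra_light)
  wrong <- search_crosslinks(st_spectra, sim$truth$proteins, "C",
                             params = par)
  if (nrow(wrong)) {
    key_w <- xl_key(wrong$alpha_accession, wrong$alpha_protein_site,
                    wrong$beta_accession, wrong$beta_protein_site)
    expect_equal(sum(key_t %in% key_w), 0)
  } else {
    succeed()
  }
  # linear-peptide spectra do not produce confident crosslinks
  lin_spectra <- Filter(function(s) grepl("_site", s$spectrum_id),
                        sim$spectra_light)[1:4]
  lin <- search_crosslinks(lin_spectra, sim$truth$proteins, "ST",
                           params = par)
  if (nrow(lin)) {
    key_l <- xl_key(lin$alpha_accession, lin$alpha_protein_site,
                    lin$beta_accession, lin$beta_protein_site)
    expect_equal(sum(key_t %in% key_l), 0)
  } else {
    succeed()
  }
})
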