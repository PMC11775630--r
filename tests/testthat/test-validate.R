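mk_csm <- function(id, mass, rt, label = "light", q = 0) {
  data.frame(spectrum_id = id, run_id = "r", label_state = label,
             alpha_peptide = "SPVVSGDTSPR", alpha_mods = "",
             alpha_accession = "MAPT", alpha_protein_site = 400L,
             beta_peptide = "CGSKDNIK", beta_mods = "",
             beta_accession = "MAPT", beta_protein_site = 291L,
             donor_site = 5L, acceptor_site = 1L, chemistry = "ST",
             precursor_mass = mass, rt = rt, score = 20, q_value = q,
             mass_error_ppm = 0, link_class = "intra")
}

test_that("heavy/light pairing requires the +8 Da crosslink signature", {
  m <- 1945.952739
  light <- mk_csm("L1", m, 50)
  # correct +8 shift, 2 ppm off, 2 min away: pairs
  heavy8 <- mk_csm("H1", m + label_18O_shift(2) + m * 2e-6, 52, "heavy")
  ev <- pair_heavy_light(light, heavy8)
  expect_true(ev$has_heavy_partner)
  expect_equal(ev$heavy_spectrum_id, "H1")
  # +4 Da is the linear-peptide signature: rejected
  heavy4 <- mk_csm("H2", m + label_18O_shift(1), 52, "heavy")
  expect_false(pair_heavy_light(light, heavy4)$has_heavy_partner)
  # retention time outside the window: rejected
  heavy_far <- mk_csm("H3", m + label_18O_shift(2), 75, "heavy")
  expect_false(pair_heavy_light(light, heavy_far)$has_heavy_partner)
  # different link site never pairs
  other <- mk_csm("H4", m + label_18O_shift(2), 50, "heavy")
  other$alpha_protein_site <- 262L
  expect_false(pair_heavy_light(light, other)$has_heavy_partner)
})

test_that("pairing is symmetric under swapping label roles", {
  m <- 1500.5
  light <- rbind(mk_csm("L1", m, 30), mk_csm("L2", m + 100, 60))
  heavy <- rbind(mk_csm("H1", m + label_18O_shift(2), 31, "heavy"),
                 mk_csm("H2", m + 250, 60, "heavy"))
  fwd <- pair_heavy_light(light, heavy)
  # reverse direction: treat heavy as the reference with a -8 expectation,
  # equivalently shift the heavy masses down and swap arguments
  heavy_shift <- heavy
  heavy_shift$precursor_mass <- heavy_shift$precursor_mass -
    2 * label_18O_shift(2)
  rev <- pair_heavy_light(heavy_shift, light)
  expect_equal(fwd$has_heavy_partner, c(TRUE, FALSE))
  expect_equal(rev$has_heavy_partner, c(TRUE, FALSE))
})

test_that("isotope similarity is 1 on self, 0 on disjoint, robust to noise", {
  comp <- peptide_composition(peptidoform("CGSKDNIK"))
  th <- isotope_pattern(comp, charge = 2, n_peaks = 5)
  obs <- cbind(th$peaks$mz, th$peaks$intensity * 1e7)
  expect_equal(isotope_similarity(obs, th), 1.0, tolerance = 1e-12)
  disjoint <- cbind(th$peaks$mz + 5, th$peaks$intensity)
  expect_equal(isotope_similarity(disjoint, th), 0)
  set.seed(4)
  for (i in 1:20) {
    noisy <- cbind(th$peaks$mz,
                   th$peaks$intensity * (1 + rnorm(5, 0, 0.05)))
    expect_gt(isotope_similarity(noisy, th), 0.99)
  }
  expect_error(isotope_similarity(obs, structure(
    list(peaks = data.frame(mass = numeric(), intensity = numeric()),
         charge = 0L), class = "isotope_pattern")), "empty")
})

test_that("acceptance requires all three criteria and is monotone", {
  base <- mk_csm("L1", 1945.952739, 50)
  base$has_heavy_partner <- TRUE
  base$ms1_similarity <- 0.99
  base$ms1_mass_error_ppm <- 1.5
  base$full_proteome_q_light <- 0.001
  base$full_proteome_q_heavy <- 0.002
  ok <- accept_crosslinks(base)
  expect_true(ok$accepted)
  no_heavy <- base; no_heavy$has_heavy_partner <- FALSE
  r <- accept_crosslinks(no_heavy)
  expect_false(r$accepted); expect_false(r$crit_heavy_pair)
  bad_q <- base; bad_q$full_proteome_q_light <- 0.02
  r <- accept_crosslinks(bad_q)
  expect_false(r$accepted); expect_false(r$crit_full_proteome_fdr)
  bad_ms1 <- base; bad_ms1$ms1_similarity <- 0.8
  expect_false(accept_crosslinks(bad_ms1)$accepted)
  # monotone: tightening any parameter never accepts a rejected link
  loose <- pairing_params(rt_window = 10, mass_tol_ppm = 20,
                          isotope_similarity_min = 0.9,
                          full_proteome_q_max = 0.05)
  tight <- pairing_params(rt_window = 2, mass_tol_ppm = 5,
                          isotope_similarity_min = 0.99,
                          full_proteome_q_max = 0.005)
  set.seed(12)
  for (i in 1:50) {
    ev <- base
    ev$has_heavy_partner <- runif(1) < 0.8
    ev$ms1_similarity <- runif(1, 0.85, 1)
    ev$ms1_mass_error_ppm <- rnorm(1, 0, 8)
    ev$full_proteome_q_light <- runif(1, 0, 0.05)
    ev$full_proteome_q_heavy <- runif(1, 0, 0.05)
    a_loose <- accept_crosslinks(ev, loose)$accepted
    a_tight <- accept_crosslinks(ev, tight)$accepted
    expect_true(!a_tight || a_loose)
  }
})

test_that("planted light-only crosslinks are all rejected end to end", {
  sim <- small_sim()
  res <- discover_crosslinks(sim$spectra_light, sim$spectra_heavy,
                             sim$truth$proteins)
  ev <- res$evidence
  tr <- sim$truth$crosslinks
  key_t <- xl_key(tr$donor_accession, tr$donor_protein_pos,
                  tr$acceptor_accession, tr$acceptor_protein_pos)
  key_e <- xl_key(ev$alpha_accession, ev$alpha_protein_site,
                  ev$beta_accession, ev$beta_protein_site)
  light_only <- key_t[!tr$in_heavy]
  expect_equal(sum(light_only %in% key_e[ev$accepted]), 0)
  # links simulated in both label states are accepted
  both <- key_t[tr$in_heavy]
  expect_gte(mean(both %in% key_e[ev$accepted]), 0.8)
})
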