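test_that("peptide compositions sum residue formulas plus water", {
  expect_equal(unclass(peptide_composition(peptidoform("G")))[c("C","H","N","O")],
               c(C = 2, H = 5, N = 1, O = 2))
  # oracle: published residue formulas summed by hand
  expect_equal(unclass(peptide_composition(peptidoform("CGSKDNIK")))[
                 c("C", "H", "N", "O", "S")],
               c(C = 34, H = 61, N = 11, O = 13, S = 1))
  expect_equal(unclass(peptide_composition(peptidoform("GG")))[c("C","H","N","O")],
               c(C = 4, H = 8, N = 2, O = 3))
  expect_error(peptidoform("GXZ"), "unknown residue")
})

test_that("composition arithmetic is commutative and guards negatives", {
  a <- composition(C = 2, H = 4, O = 1)
  b <- composition(H = 2, O = 1)
  expect_equal(unclass(comp_add(a, b)), unclass(comp_add(b, a)))
  expect_error(comp_subtract(b, a), "negative")
  expect_equal(monoisotopic_mass(comp_add(a, b)),
               monoisotopic_mass(a) + monoisotopic_mass(b), tolerance = 1e-12)
  expect_error(composition(H = -1), "negative")
  expect_equal(monoisotopic_mass(composition()), 0)
})

test_that("monoisotopic masses match the pinned atomic-mass table", {
  expect_equal(monoisotopic_mass(composition(H = 2, O = 1)), 18.010565,
               tolerance = 1e-6)
  expect_equal(monoisotopic_mass(composition(H = 2, S = 1)), 33.987721,
               tolerance = 1e-6)
})

test_that("m/z conversion uses the proton mass and round-trips", {
  expect_equal(mz_from_mass(1000, 1), 1001.007276, tolerance = 1e-6)
  expect_equal(mz_from_mass(1945.952739, 4), 487.49546, tolerance = 1e-5)
  m <- 1234.5678
  expect_equal(mass_from_mz(mz_from_mass(m, 3), 3), m, tolerance = 1e-9)
  expect_error(mz_from_mass(100, 0), "positive")
})

test_that("eliminylation deltas are -H2O for S/T and -H2S for C", {
  expect_equal(eliminylation_delta("S"), -18.010565, tolerance = 1e-6)
  expect_equal(eliminylation_delta("T"), eliminylation_delta("S"))
  expect_equal(eliminylation_delta("C"), -33.98772, tolerance = 5e-6)
  expect_error(eliminylation_delta("A"), "eliminylatable")
})

test_that("conjugate deltas equal eliminylation plus intact nucleophile", {
  expect_equal(conjugate_delta("GSH", "S"), 289.073241, tolerance = 1e-6)
  expect_equal(conjugate_delta("HC", "S"), 117.024835, tolerance = 1e-6)
  expect_equal(conjugate_delta("DTT", "C"), 120.024499, tolerance = 1e-6)
  # S vs C routes differ exactly by the H2S/H2O difference
  expect_equal(conjugate_delta("TCEP", "C") - conjugate_delta("TCEP", "S"),
               eliminylation_delta("C") - eliminylation_delta("S"),
               tolerance = 1e-9)
  expect_error(conjugate_delta("XYZ", "S"), "unknown conjugate")
})

test_that("18-O label shifts are ~4 Da per labelled terminus", {
  expect_equal(label_18O_shift(0), 0)
  expect_equal(label_18O_shift(1), 4.00849, tolerance = 1e-5)
  expect_equal(label_18O_shift(2), 8.016983, tolerance = 1e-5)
  expect_error(label_18O_shift(3), "0, 1 or 2")
})

test_that("crosslink species mass is additive and swap-symmetric", {
  mods <- built_in_modifications()
  a <- peptidoform("SPVVSGDTSPR")
  b <- peptidoform("CGSKDNIK")
  xl <- crosslink_species(a, b, 5, 1, mods[["XL[ST]"]])
  expect_equal(monoisotopic_mass(xl),
               monoisotopic_mass(a) + monoisotopic_mass(b) +
                 eliminylation_delta("S"), tolerance = 1e-9)
  expect_equal(mz_from_mass(monoisotopic_mass(xl), 4), 487.49546,
               tolerance = 1e-5)
  # the companion standard computes to 427.47400 by residue-mass
  # summation (not the transposed 474.47400)
  xl2 <- crosslink_species(peptidoform("IGSTENLK"), b, 3, 1, mods[["XL[ST]"]])
  expect_equal(monoisotopic_mass(xl2), 1705.866884, tolerance = 1e-5)
  expect_equal(mz_from_mass(monoisotopic_mass(xl2), 4), 427.47400,
               tolerance = 1e-5)
  # swap symmetry: two peptides that can each act as donor and acceptor
  p1 <- peptidoform("CGSKDNIK")   # donor C1, acceptor K4
  p2 <- peptidoform("TACHLLK")    # donor C3, acceptor H4
  fwd <- crosslink_species(p1, p2, 1, 4, mods[["XL[C]"]])
  bwd <- crosslink_species(p2, p1, 3, 4, mods[["XL[C]"]])
  expect_equal(monoisotopic_mass(fwd), monoisotopic_mass(bwd),
               tolerance = 1e-12)
})

test_that("crosslink species rejects bad chemistry", {
  mods <- built_in_modifications()
  a <- peptidoform("SPVVSGDTSPR")
  b <- peptidoform("CGSKDNIK")
  expect_error(crosslink_species(a, b, 2, 1, mods[["XL[ST]"]]), "donor")
  expect_error(crosslink_species(a, b, 5, 2, mods[["XL[ST]"]]), "acceptor")
  # alkylated linking cysteine is chemically blocked
  b_cam <- peptidoform("CGSKDNIK",
                       list(`1` = mods[["Carbamidomethyl"]]))
  expect_error(crosslink_species(a, b_cam, 5, 1, mods[["XL[ST]"]]),
               "alkylated")
})

test_that("modification definitions enforce composition/mass consistency", {
  expect_error(modification("bad", "conjugate", "S",
                            composition(H = 2, O = 1), delta_mass = 19),
               "disagrees")
  expect_error(modification("bad", "conjugate", character(),
                            delta_mass = 1), "non-empty")
  mods <- built_in_modifications()
  for (m in mods) {
    if (is.null(m$delta_composition)) next
    expect_lt(abs(monoisotopic_mass(m$delta_composition) - m$delta_mass),
              1e-4)
  }
})

test_that("modification YAML round trip preserves the registry", {
  mods <- built_in_modifications()
  path <- tempfile(fileext = ".yml")
  on.exit(unlink(path))
  write_modifications(mods, path)
  back <- read_modifications(path)
  expect_setequal(names(back), names(mods))
  for (nm in names(mods)) {
    expect_equal(back[[nm]]$delta_mass, mods[[nm]]$delta_mass,
                 tolerance = 1e-6)
    expect_setequal(back[[nm]]$targets, mods[[nm]]$targets)
    expect_equal(back[[nm]]$mod_class, mods[[nm]]$mod_class)
  }
})

test_that("heavy C-terminus shifts peptidoform mass by the double label", {
  light <- peptidoform("IGSTENLK")
  heavy <- peptidoform("IGSTENLK", c_term_heavy_O = 2L)
  expect_equal(monoisotopic_mass(heavy) - monoisotopic_mass(light),
               label_18O_shift(1), tolerance = 1e-9)
  expect_equal(monoisotopic_mass(peptide_composition(heavy)),
               monoisotopic_mass(heavy), tolerance = 1e-9)
})
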