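---
title: "Methods: dehydroamino-acid crosslink discovery with dhaaxl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dehydroamino-acid crosslink discovery with dhaaxl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhaaxl)
```

## The chemistry being modelled

Dehydroamino acids (DHAAs) form in proteins by *eliminylation*: serine and
threonine lose water (giving dehydroalanine and dehydrobutyrine,
−18.010565 Da), and cysteine loses hydrogen sulphide (−33.987721 Da).
Phosphorylated precursors eliminate to the same products, so the mass delta
relative to the unmodified residue is identical either way.  The resulting
electrophilic alkene undergoes Michael addition with nucleophiles:

* small cellular nucleophiles — glutathione (GSH) and homocysteine (HC) —
  or workflow reducing agents (DTT, TCEP), giving *conjugates* whose delta
  is `eliminylation delta + intact nucleophile mass`
  (`conjugate_delta("GSH", "S")` = +289.073241 Da);
* nucleophilic side chains (Cys, Lys, His) of another peptide chain, giving
  a protein–protein crosslink whose species mass is
  `mass(alpha) + mass(beta) + eliminylation delta`.

Michael addition is treated as mass-neutral bond formation (the adduct is
the exact sum); stereochemistry is mass-identical and ignored.
Dehydrobutyrine is handled identically to dehydroalanine in mass terms,
since one crosslinker delta covers both S- and T-derived DHAAs.

All arithmetic runs on a pinned monoisotopic atomic-mass table
(NIST/IUPAC values, proton mass 1.00727646688 Da) so results are identical
across platforms.  The commonly quoted crosslinker constant −18.0105 is
treated as a truncated rendering of −18.010565; only the full-precision
value reproduces
the crosslinked-standard m/z of 487.49546 (z = 4).  The companion standard
IG[DHA]TENLK–CGSKDNIK computes to 427.47400 at z = 4 by residue-mass
summation (and by an independent brute-force oracle); the printed value
474.47400 appears to be a digit transposition and is not used.

## The ¹⁸O validation strategy

Tryptic digestion in heavy water installs two ¹⁸O atoms on each newly
created C-terminal carboxylate: +4.00849 Da per labelled terminus.  A
linear peptide has one labelled terminus (+4 Da nominal); a crosslinked
pair of peptides has two (+8 Da nominal).  This is the discriminating
signature: a candidate crosslink must appear in the standard digestion at
mass M and in the heavy digestion at M + 8.016980 Da within tolerance and
within a retention-time window.  A +4 Da partner is the linear-peptide
signature and is rejected.

The heavy label is carried as a distinct element species (`O18`) through
composition arithmetic, so theoretical isotope patterns, fragment masses
(label in all y ions, never in b ions) and precursor masses stay
consistent.

## Search engine

The engine is a transparent, testable stand-in for a production search
tool, scored on planted-truth recovery rather than engine benchmarking:

* candidates come from an in-silico tryptic digest (cleave after K/R, not
  before P; default 2 missed cleavages, length 6–40) of targets plus
  reversed decoys (C-terminal residue kept in place, preserving the
  tryptic mass distribution);
* fixed modifications (carbamidomethyl by default; propionamide
  selectable) apply everywhere eligible; a variable or discovered
  modification *displaces* a fixed alkylation at its site, because an
  eliminylated or conjugated cysteine cannot also be alkylated;
* scoring is greedy nearest-peak matching within a ppm tolerance, each
  observed peak usable once; score = matched ion count + fraction of
  intensity explained.  Defaults: 10 ppm precursor, 20 ppm fragment,
  fragment charges 1–2, b/y ions only;
* q-values are standard target-decoy: `#decoys ≥ s / #targets ≥ s`,
  capped at 1 and monotonized; results filter at 1% FDR.

The open (delta-mass) discovery pass matches unexplained precursor deltas
against a candidate modification list and localizes each hit to the target
residue maximizing the fragment score (ties resolve to the lowest
position).  Because a discovered modification can displace a fixed
alkylation, the expected delta is position-dependent.

The crosslink search enumerates (alpha, beta) peptide pairs from a
mass-sorted index such that `mass(alpha) + mass(beta) + delta` matches the
precursor, with alpha containing a donor residue of the requested
chemistry (S/T or C) and beta an acceptor (C/K/H); a linking cysteine's
alkylation is stripped from both the pairing mass and the species.  Pairs
are scored on the union of both chains' fragments, where ions spanning the
linked site carry the entire partner mass plus the crosslinker delta.
Two design rules matter for false-positive control:

* a CSM must have at least two matched fragment ions on *each* chain —
  matches supported by a single peptide are the classic crosslink
  false-positive mode;
* the pipeline pools the S/T- and C-chemistry searches with decoys
  retained, keeps the best explanation per spectrum, and estimates
  q-values on that pooled list.  Without per-spectrum competition, a
  spectrum whose true explanation lives in the other chemistry search can
  contribute a high-scoring decoy that inflates q-values for genuine
  low-scoring links.

Site localization ties are broken toward the lowest position and flagged
ambiguous, mirroring the "S244|T246"-style ambiguity notation used in
reporting.  For a crosslink between two cysteines the donor/acceptor
orientation is mass- and fragment-identical either way, so links are
compared as unordered site pairs.

## The three-criterion acceptance rule

A candidate crosslink is accepted only if:

1. a heavy partner exists: same peptide pair and linked sites, mass
   difference 8.016980 Da within tolerance (default 10 ppm), retention
   times within the window (default 5 min);
2. the MS1 evidence agrees with theory: observed monoisotopic mass within
   tolerance *and* normalized-dot-product similarity of the observed MS1
   isotope block against the theoretical isotope distribution at least
   0.95;
3. both light and heavy forms are re-found below 1% FDR in a standard
   linear search against the full proteome, in which each candidate
   crosslink is appended as a site-specific custom modification whose
   delta is the partner-peptide mass plus the crosslinker delta (heavy
   variant: plus the partner's +4.00849 labelled C-terminus).

The retention-time window, mass tolerance and similarity threshold are not
quantified in the source description ("acceptable"); the defaults above
are deliberately strict and are plain function arguments.  Acceptance is
monotone: tightening any parameter never accepts a previously rejected
link (property-tested).

## Statistics

*Differential abundance.* Fold changes are ratios of group means on the
raw intensity scale (matching the "x-fold higher" reporting style);
confidence comes from a two-tailed t-test on log2 intensities.  The source
describes a *paired* t-test for 48 AD vs 44 control specimens — pairing is
impossible at unequal sizes — so the default is the Welch two-sample test,
with a paired mode available for genuinely matched, balanced designs.
Missing intensities are treated as absent: features with fewer than two
values in either group are skipped with a reason, never imputed, because
any imputation choice would dominate the result.  Zero-variance features
report the limiting p-value (1 for equal means, 0 otherwise) with a
`degenerate_zero_variance` flag instead of erroring.

*Permutation FDR.* Group labels are permuted without restriction; for each
observed |t| threshold, the expected number of permuted |t| values
exceeding it (mean over permutations, all features pooled) is divided by
the observed exceedance count.  The estimate is capped at 1 and converted
to q-values by taking, per feature, the minimum FDR over call sets
containing it.  The computation is deterministic given a seed and
invariant to feature order; an exhaustive mode enumerates all label
assignments for small designs and is checked against an independent
enumeration oracle at 3 vs 3.

*Site calling and prevalence.* A site is a confirmed eliminylation site
only when at least one conjugate form (GSH, HC, DTT, TCEP or a crosslink)
is observed there; direct −18/−34 Da losses alone are retained but flagged
unconfirmed, since in-source loss can generate them artifactually.
Prevalence thresholds are inclusive fractions of the specimen universe, so
counts are non-increasing in the threshold.

*Occupancy.* Per specimen, occupancy = modified / (modified + unmodified)
intensity; the summary is the mean across specimens with its standard
error (checked against a bootstrap over specimens).

*Label-free quantification* is aggregation, not feature detection:
feature intensity per specimen is the sum of precursor intensities over
that specimen's runs, followed by median normalization across specimens.

## The synthetic-data generator

The generator defines the benchmark conditions and is itself first-class,
tested code.  It emulates:

* tryptic-friendly random proteomes (segments of 5–14 residues ending in
  K/R; optionally the three synthetic-standard peptides embedded as
  tryptic windows);
* planted direct DHAA sites, conjugate sites per nucleophile, and
  intra/inter crosslinks on chemistry-eligible residues without collision;
* paired light/heavy runs (default 2 per study, emulating fractionation at
  desk scale): one spectrum per planted species per run, Gaussian ppm mass
  error (default 2 ppm), theoretical b/y and crosslink-carrying fragments,
  uniform noise peaks, an MS1 isotope block from the exact composition,
  and retention times consistent between paired runs (0.5 min jitter);
* incomplete ¹⁸O exchange: with probability 0.05 (95% isotopic purity) a
  heavy species retains one light oxygen, a deliberate stress for the
  validator, which matches only the fully exchanged +8 species;
* light-only planted crosslinks as negative controls for the ¹⁸O
  criterion;
* AD/CTR intensity matrices (48 vs 44 specimens) with log-normal noise
  (sigma 0.3 on the log scale) and a planted 10-fold AD elevation on
  crosslink features.

One deliberate constraint: intra-protein crosslinks between *adjacent*
tryptic peptides are never planted.  With a −H2O crosslinker such a
species is exactly isobaric with the missed-cleavage linear peptide, so
the light-state full-proteome re-search cannot distinguish them even in
principle — only the heavy state (+8 vs +4) separates them.  Real accepted
links of this chemistry are between non-adjacent peptides.

What the simulator does **not** model — and therefore what passing tests
do not demonstrate about real data: chromatographic peak shapes and
co-elution, chimeric spectra, ionization efficiency and missingness
structure, mass miscalibration (inputs are assumed calibrated),
off-target modifications beyond the configured set, and realistic protein
sequence composition.  Planted-truth recovery shows the machinery is
correct, not that the engine rivals production search tools on real
spectra.

## Numerical choices

* Isotope patterns: per-element polynomial convolution over
  nucleon-offset bins with intensity-weighted centroid masses; relative
  truncation 1e-10 during convolution; final pattern renormalized to sum
  1 after cutting to `n_peaks`.  Checked against exhaustive isotopologue
  enumeration for compositions up to ~12 atoms (max intensity deviation
  < 1e-9).
* The installed ¹⁸O label is treated as isotopically pure in pattern
  computation; the 95% purity of the digestion water is a simulator
  property, not a pattern property.
* Greedy fragment matching processes theoretical ions in ascending m/z,
  making the score deterministic and invariant to spectrum peak order.
* Tie-breaks: equal-scoring candidates prefer targets over decoys, then
  the lowest index; localization ties take the lowest site and set the
  ambiguity flag.
* Degenerate inputs: empty spectra score 0; empty FASTA errors;
  subtracting atoms that are not present errors rather than clamping.

## Problem sizes

The shipped benchmarks run on one CPU at desk scale: 30 proteins of ~12
tryptic segments, 26 planted sites, 12 validated + 3 light-only planted
crosslinks, 2 paired light/heavy runs (about 110 spectra); the null
calibration uses 1000 features by 92 specimens with 100 label
permutations.  The end-to-end pipeline completes in about a minute; these
sizes are the package's chosen benchmark conditions.

## Known limitations

* The scoring model is intentionally simple (count + intensity); it has
  no intensity prediction, no rescoring, and no support for chimeric
  spectra.
* Crosslink searches assume targeted databases of at most a few hundred
  proteins; the pair enumeration is quadratic in peptides at a given
  mass.
* Only b/y ions at charges 1–2 are generated (HCD-style fragmentation).
* mzML/mzIdentML and vendor formats are out of scope; I/O is FASTA, MGF
  and TSV.
* The aggregation-panel protein list shipped in `inst/extdata` is
  editable configuration seeded with well-known aggregating proteins, not
  a ground-truth enumeration.
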