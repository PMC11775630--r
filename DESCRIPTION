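Package: dhaaxl
Title: Discovery and Validation of Dehydroamino-Acid Crosslinks in
    Bottom-Up Proteomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying dehydroamino acids (DHAAs), their
    nucleophile conjugates, and DHAA-mediated protein-protein crosslinks
    in bottom-up mass-spectrometry proteomics data.  Provides monoisotopic
    mass arithmetic and theoretical isotope patterns for eliminylation
    chemistry; readers and writers for FASTA, MGF and tab-separated
    identification tables; in-silico tryptic digestion and crosslink
    search planning; a transparent linear and crosslink search engine
    with target-decoy false-discovery-rate control and open
    (delta-mass) modification discovery; heavy/light (18-O C-terminal
    label) crosslink validation against theoretical isotope
    distributions; conjugate-evidence eliminylation-site calling,
    specimen prevalence summaries, label-free quantification,
    permutation-FDR differential abundance and site occupancy; and a
    seeded synthetic-data generator with planted ground truth for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
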