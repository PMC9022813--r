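Package: rsdna
Title: Hybridization Thermodynamics and Pairing Statistics of
    Random-Sequence DNA Oligomer Pools
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical-thermodynamic model of duplex formation in pools of
    random-sequence DNA oligomers, where all 4^L sequences of length L
    compete for partners. Provides sequence-specific nearest-neighbor free
    energies for complementary duplexes, a composition-averaged
    re-parametrization of the nearest-neighbor model keyed on a duplex
    defect vector (shift, terminal mismatches, internal mismatches),
    combinatorial degeneracy counting, parameter-free prediction of
    ensemble melting curves and melting temperatures, defect-class pairing
    statistics, and the fraction of a spiked fluorophore-tagged
    complementary pair that hybridizes amid the competing pool
    (contact-quenching model). Includes absorbance melting-curve
    normalization, a synthetic absorbance fixture generator, FASTA/CSV
    input-output and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
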