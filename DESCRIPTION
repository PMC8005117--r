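Package: pkiprofiler
Title: Profiling Protein Kinase Inhibitors: Descriptors, the
    Hydrogen-Bond/Aromatic-Ring Exchange Rule, and Binding-Site
    Pi-Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for chemoinformatic profiling of protein kinase
    inhibitors (PKIs). Computes a compact molecular descriptor set
    (including the size-normalised weighted hydrogen bond count, WHBC,
    and the fraction of sp3 carbons), evaluates Lipinski rule-of-five
    and Veber bioavailability compliance, bins ligand cohorts by
    aromatic ring count and fits the inverse-linear trend of mean WHBC
    versus ring count (the hydrogen-bond/aromatic-ring exchange rule),
    detects and classifies non-bonded pi-interaction modes (pi-pi,
    CH-pi, cation-pi, NH/OH/SH-pi, hydrogen bonds, salt bridges) in
    kinase-inhibitor complexes from PDB coordinates, and performs the
    thermodynamic-cycle bookkeeping that combines gas-phase interaction
    energies with dehydration penalties into aqueous-phase interaction
    energies grouped by interaction mode. Includes seeded synthetic
    generators for ligand cohorts, complex fixtures and energy ledgers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
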