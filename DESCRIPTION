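Package: clipstereo
Title: Stereochemistry Resolution for NRPS Cyclic Lipodepsipeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Resolves the D/L configuration of cyclic lipodepsipeptides
    (CLiPs) assembled by non-ribosomal peptide synthetases (NRPS).
    Predicts per-residue configuration from condensation-domain
    architecture (C_start, dual epimerization/condensation E/C, and
    LCL domains), enumerates the diastereomer candidates consistent
    with Marfey's composition counts under hard positional constraints
    and epimerization-activity priors, dereplicates compounds by
    optimal one-to-one matching of HSQC CH-alpha chemical-shift
    fingerprints, scans condensation-domain protein sequences for the
    primary (HHxxxDG / HHxxxDH) and N-terminal secondary (HH[I/L]xxxxGD)
    histidine motifs with single-insertion tolerance and flags atypical
    histidine flanks, and simulates ground-truthed inputs for every
    stage, including assembly lines with an intermittently active E/C
    domain that yields two diastereomeric products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
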