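Package: absalt
Title: Arginine Salt-Bridge Analysis for Amyloid-Beta Ensembles and NMR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising transient N-terminal arginine salt
    bridges in intrinsically disordered peptides such as amyloid-beta (1-40).
    Fits the pressure dependence of chemical shifts to a second-order Taylor
    expansion with random-coil correction and classifies per-residue pressure
    response; detects and mode-classifies arginine guanidinium to
    aspartate/glutamate carboxylate salt bridges (side-on, end-on, backside)
    across multi-conformer ensembles, with occupancies, simultaneous-bridging
    fractions, and bridge-conditional Calpha-Calpha distance statistics;
    simulates and fits chemical exchange saturation transfer (CEST) profiles
    under a two-site symmetric-exchange Bloch-McConnell model to recover
    guanidinium rotational exchange rates and nitrogen shift differences; and
    summarises per-conformer phosphorylation energy tables into group
    comparisons. A seeded synthetic-data module generates shift tables,
    reduced-atom conformer ensembles with planted bridges, CEST profiles, and
    energy tables with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    broom,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
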