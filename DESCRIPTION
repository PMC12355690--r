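Package: cocryst
Title: In Silico Cocrystal Screening, Synthon Energies, Morphology and
    Facet Surface Chemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A computational workflow for pharmaceutical cocrystal design:
    stage-1 coformer screening by molecular complementarity (bounding-box
    shape and polarity descriptors with PASS/FAIL gating), stage-2 ranking
    by hydrogen-bond-propensity difference with a logistic surrogate
    propensity model, crystal-packing synthon analysis under a
    Dreiding-style force field (Lennard-Jones 12-6, distance-dependent
    dielectric Coulomb, explicit 12-10 hydrogen-bond term), attachment-energy
    morphology prediction with a Wulff habit construction, and
    facet-specific surface characterization (hydrogen-bond donor/acceptor
    and aromatic bond densities, rugosity from van der Waals height maps).
    Includes deterministic synthetic-data generators for molecules,
    H-bonded ribbon crystals, coformer libraries and propensity tables so
    the whole pipeline runs without external structure databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    stats,
    utils,
    generics
Suggests:
    ChemmineR,
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
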