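Package: gradsip
Title: DNA Stable-Isotope-Probing Analysis of Gas-Fed Soil Microcosms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for DNA stable-isotope-probing (DNA-SIP)
    experiments that identify gas-oxidizing bacteria in soil microcosms:
    headspace gas depletion accounting with abiotic-loss correction,
    per-taxon buoyant-density profiles across CsCl gradient fractions and
    classification of isotopically labeled taxa, absolute functional-gene
    quantification from qPCR standard curves with ratio normalization and
    labeling-shift detection, clone-library clustering into operational
    protein families with alpha-diversity estimation (Chao1, Shannon,
    Good's coverage, analytic rarefaction), and chi-square correspondence
    analysis of community composition with segment-wise detrending. A
    forward simulator of the whole labeling experiment (community, gas
    kinetics, isotope incorporation, gradient banding, amplicon counts,
    qPCR, clone libraries) provides fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
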