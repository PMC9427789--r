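Package: abscan
Title: Alanine-Scanning-Guided Assessment of Antibody-Antigen Docking Poses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for mapping antibody-antigen interfaces by combining
    alanine-scanning mutagenesis with the structural assessment of docking
    poses. Provides a Shrake-Rupley solvent-accessible surface area engine
    with relative-accessibility-based selection of scan positions, Chothia
    CDR annotation of Fv models, four-parameter-logistic fitting of ELISA
    binding curves with censored fold-change classification, construction of
    epitope/paratope restraint scenarios for data-driven docking, PISA-style
    buried-surface-area and per-region interface partitions, receptor-blockage
    analysis by rigid superposition, concordance scoring of poses against
    mutagenesis data, a seven-criterion filter-and-rank procedure for pose
    selection, cross-species epitope conservation analysis with back-mutation
    proposals, and synthetic-structure generators so that the whole pipeline
    can be exercised with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
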