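Package: mapksurvey
Title: Genome-Wide Survey Toolkit for Plant MAPK and MAPKK Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide surveys of mitogen-activated
    protein kinase (MAPK) and MAPK kinase (MAPKK) gene families in plants.
    Validates candidate gene models by activation-loop and active-site motif
    rules (TEY/TDY/MEY, D(I/L/V)K, S/T-X5-S/T, CD docking domain), calls
    tandem and segmental duplications from alignment coverage and identity,
    detects chromosomal gene clusters, maps family members onto synteny
    blocks, scans 1-kb promoters for stress-responsive cis-elements (W-box,
    CBF, DRE, GCC), builds bootstrap neighbor-joining trees from corrected
    distances, and processes expression matrices (quantile normalization,
    paired-test differential-expression calls, ortholog-pair Pearson
    correlation). Ships seeded synthetic-data generators with exact ground
    truth so every stage is testable without external downloads, and packaged
    nomenclature and pair-correlation fixtures for the Brachypodium
    distachyon MAPK/MAPKK families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    ape,
    limma,
    jsonlite,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
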