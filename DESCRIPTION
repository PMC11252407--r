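Package: osmoscreen
Title: Quantitative Pipelines for Multi-Omics Osmotic-Stress Screens in Chlamydomonas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical and image-quantification pipelines for genome-wide
    osmotic-stress studies in the green alga Chlamydomonas reinhardtii.
    Implements hit calling for pooled barcoded insertional-mutant fitness
    screens (phenotype ratios binned into contingency tables, gene-versus-
    background exact conditional tests, Benjamini-Hochberg FDR), Z-score
    scoring of 96-well secondary plate screens, reciprocal 14N/15N
    label-swap phosphopeptide filtering, reciprocal-best-BLAST-hit
    orthology mapping with overlap and enrichment statistics, and
    microscopy quantification operators (actin intensity skewness,
    filament angle by structure tensor, maximum-entropy thresholding,
    calcium spike detection, plasmolysis shrinkage). Every input has a
    synthetic generator with known ground truth so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
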