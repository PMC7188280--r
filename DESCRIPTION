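Package: breedgain
Title: Selection-Strategy Comparison for Grain Yield in Inbred Crop Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare truncation-selection strategies in inbred-line
    breeding programs: augmented complete block design adjustment of plot
    yields (BLUEs per environment, REML BLUPs across environments),
    ridge-regression BLUP (RRBLUP) genomic prediction with optional
    GWAS-derived fixed-effect markers, kinship-corrected single-marker
    association scans with Benjamini-Hochberg FDR control, Rogers genetic
    distances, and response-to-selection accounting (R = H^2 * S) for
    phenotypic, marker-based, genomic, and combined selection.  Includes a
    breeding-population simulator (founder panels, F5 and doubled-haploid
    biparental progeny, multi-environment trials with genotype-by-environment
    interaction) so the full pipeline can be exercised and validated on
    synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
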