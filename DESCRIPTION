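Package: hsp90cl
Title: Phosphosite Occupancy, Interactome and Secretion Analyses for
    Hsp90beta Charged-Linker Phosphorylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis pipeline for studying phosphorylation of
    the charged linker of human Hsp90beta (S226/S255): phosphosite occupancy
    from SILAC heavy/light ratio triplets measured by parallel reaction
    monitoring, differential AP-MS interactome calling from MaxQuant-style
    protein-group tables (label-free iBAQ and SILAC ratio modes), limited
    proteolysis conformational readouts from gel-band peptide intensities,
    and secretion/probe-binding quantification from capillary western
    signals.  A synthetic-data module forward-simulates every assay with
    known ground truth so all stages are verifiable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
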