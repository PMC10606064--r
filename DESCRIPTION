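Package: tauassay
Title: Binding, Aggregation, Viability, Migration and Imaging Assays for
    Tau-Targeted Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of the in vitro and cellular assays used
    to characterise small molecules directed against the microtubule
    associated protein Tau.  Implements inner-filter correction and
    modified Stern-Volmer analysis of tyrosine fluorescence-quenching
    titrations (accessible fraction and dissociation constant),
    exponential-plateau fitting of thioflavin-S aggregation time courses
    with percent-inhibition and log10-linear IC50 estimation, Chou-Talalay
    median-effect analysis of MTT viability plates, per-track cell
    migration metrics (velocity, distance to origin, directional
    persistence) with group summaries, and Otsu-threshold quantification
    of the microtubule surface fraction of single cells.  A seeded
    synthetic-data module generates every input type with known ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
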