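Package: cannmrm
Title: Targeted LC-MS/MS Pipeline for Cannabinoid Metabolites in Whole Blood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multiple-reaction-monitoring
    (MRM) quantification of Delta-9-THC, HHC and their hydroxy and carboxy
    metabolites in whole blood. Implements exact isotopologue distributions from
    molecular formulas and a hypergeometric fragment-retention model for the
    M+2 isobaric interference of 13C2-THC-COOH on the HHC-COOH channels;
    windowed chromatographic peak integration with epimer resolution;
    forensic identification criteria (retention time, quantifier/qualifier ion
    ratio, area cutoffs) with internal-standard recovery exclusions;
    internal-standard calibration, correction-factor semi-quantification for
    analytes lacking reference material, and LLOQ censoring; cohort grouping,
    prevalence and concentration summaries; and qualitative detection calls for
    human liver microsome incubation time series. A synthetic-data generator
    with recorded ground truth supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    yaml,
    deSolve,
    generics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
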