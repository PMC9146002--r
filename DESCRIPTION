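Package: senespec
Title: Spectroscopic Profiling of Replicative Senescence in Cultured Fibroblasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling replicative senescence in long-term cultures
    of primary human fibroblasts from three complementary readouts: ATR-FTIR
    absorbance spectra of whole cells, 1H-NMR spectra of the endo- and
    exometabolome, and lamin-B1 immunofluorescence of nuclei. Implements the
    full FTIR preprocessing chain (region extraction, rubberband baseline
    correction, area normalization, Savitzky-Golay second derivatives, PCA
    Q-residual outlier screening), NIPALS PLS1 regression against passage
    number with cross-validation, beta-coefficients and VIP scores, the eight
    second-derivative band-ratio senescence indices, a simplified NMR
    processing pipeline with Pareto scaling and chemical-shift assignment,
    corrected total cell fluorescence (CTCF) quantification from z-stacks,
    and passage-wise group statistics. A synthetic-cohort generator emulates
    the study design (14 passages, replicate hierarchy, passage-dependent
    band trends) so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    tiff
Config/testthat/edition: 3
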