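Package: osmoquant
Title: Quantification Toolkit for Osmoadaptation Studies in Halophilic Protists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the three quantification procedures used to characterise
    the salt-out osmoadaptation strategy of halophilic heterotrophic ciliates:
    internal-standard quantitative 1H-NMR of compatible solutes (glycine
    betaine, ectoine, choline) scaled to intracellular molarity via a
    cylinder-plus-two-cones cell-volume model, including 13C-satellite analysis
    of label conversion; corrected relative fluorescence (CRF) ion imaging with
    three-stratum intensity segmentation; and Michaelis-Menten enzyme
    characterisation under salt and osmolyte stress with derived comparison
    metrics (specificity constant, residual activity, osmolyte performance).
    Ships seeded synthetic-data generators (spectra, micrographs, rate series,
    growth counts) with known ground truth, the study's statistical layer
    (Welch's t, Pearson regression, one-way ANOVA with Tukey HSD, fold
    change), plain-text readers and writers for spectra and images, and an
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
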