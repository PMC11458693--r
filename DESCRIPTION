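Package: irpheno
Title: Single-Cell Infrared Phenomics and Drug Combination Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cell Fourier-transform infrared (FTIR)
    microspectroscopy "phenomics": preprocessing of single-cell absorbance
    spectra (moving-average smoothing, linear automatic baseline correction,
    Savitzky-Golay second derivatives, Mie-scattering EMSC), construction of
    14-dimensional per-cell spectral absorption matrices partitioned into
    fatty-acid, protein and carbohydrate subregions, cell-to-cell Euclidean
    distance heterogeneity statistics, and principal component analysis of
    second-derivative spectra.  Includes a seeded synthetic single-cell
    spectrum generator for validation, and a drug-combination interaction
    module implementing the coefficient of drug interaction (CDI), Bliss
    statistical independence and highest-single-agent models together with
    four-parameter logistic IC50 fitting and dose-unit conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
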