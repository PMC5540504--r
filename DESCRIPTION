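Package: ChromDisrupt
Title: Automated HPLC Monitoring of Cell Disruption Efficiency
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for at-line monitoring of high-pressure homogenization
    of microbial biomass from UV (280 nm) anion-exchange chromatograms.
    Provides chromatogram import and validation on a uniform time grid,
    mean-reference construction and correlation-optimized integer-sample
    peak alignment (whole-trace or per interval), trapezoidal integration
    of flowthrough and elution regions, relative protein-recovery
    statistics under start- and end-anchored normalization conventions,
    reductions for reference viability analytics (plate counts, flow
    cytometry, dielectric spectroscopy) and a five-method comparison
    table, full-factorial design-of-experiments generation and screening
    model evaluation (R-squared, leave-one-out Q-squared, coefficient
    p-values, response surfaces), plus seeded simulators for two-peak
    chromatograms and multi-cycle disruption experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ChromDisrupt-package.R'
    'alignment.R'
    'chromatogram-io.R'
    'config.R'
    'doe.R'
    'quantify.R'
    'reference-analytics.R'
    'synthetic.R'
    'utils.R'
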