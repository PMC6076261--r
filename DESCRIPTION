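Package: punctaflux
Title: Quantification of Autophagy Imaging and Protease-Assay Readouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reusable quantification pipeline for autophagy drug-discovery
    readouts. Provides seeded synthetic-data generators with full ground
    truth (fluorescence microscopy fields and assay tables), high-content
    GFP-LC3 puncta scoring with live/dead classification and form-factor
    filtering, tandem mRFP-eGFP-LC3 red/yellow autophagic-flux ratios and
    Lysotracker intensity metrics, protease-assay enzymology (dose-response
    IC50, Michaelis-Menten kinetics, inhibition-mode diagnosis with global
    Ki, mass-spectrometry cleavage fractions, binding KD), western-blot
    densitometry normalization with a bafilomycin-additivity flux-block
    statistic, and noncompartmental pharmacokinetic summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
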