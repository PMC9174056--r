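Package: panthoscope
Title: Ratiometric tfLC3 Vesicle Classification and PANTHOS Lesion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies autophagy-lysosomal pathway status in multi-channel
    fluorescence images of neurons expressing the tandem mRFP-eGFP-LC3
    (tfLC3) probe. Detects vesicular puncta, converts their per-channel
    intensities into a hue angle and saturation, and classifies each vesicle
    as autophagosome (AP), acidified autolysosome (AL), poorly acidified
    autolysosome (pa-AL) or lysosome (LY) using the lysosomal-marker channel.
    Aggregates calls into per-neuron counts, sizes and colocalization
    fractions with group statistics, and detects and stages PANTHOS lesions
    (rosettes of autophagic-vacuole-filled membrane blebs around a nuclear
    remnant) including amyloid-plaque correspondence. Ships a seeded
    synthetic confocal-field generator that emulates the probe's pH-dependent
    photophysics so the whole pipeline is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
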