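Package: apicobasal
Title: Quantification of Protein Localization Along the Apical-Basal Axis of Epithelia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify fluorescent protein distribution along the
    apical-basal axis of pseudostratified epithelia from multichannel confocal
    stacks: orthogonal reslicing, rectangular-ROI intensity profile extraction,
    junctional-peak alignment and averaging, luminal background subtraction,
    correction for nanobody-induced fluorescence enhancement, compartment
    partitioning with localization fractions and Welch tests, in vitro
    titration analysis (plateau detection, fold change at saturation,
    imaging linearity), polygon-based area morphometry, and a seeded
    synthetic-scene generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
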