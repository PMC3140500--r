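Package: closuredyn
Title: Quantitative Phenotyping of Drosophila Dorsal Closure Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation-based extraction of dorsal-hole geometry from
    time-lapse fluorescence movies of Drosophila embryos, kinematic model
    fitting of the closure process (sheet translocation velocity v, zipping
    rate constant k_z, fractional zipping contribution f_z), amnioserosa
    apical-area pulsation statistics, leading-edge protrusion morphometrics
    (filopodium lengths, lamellipodium areas), and RNAi-screen penetrance and
    candidate-selection statistics. A synthetic-data generator with known
    ground truth stands in for embryo movies, so every measurement stage can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
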