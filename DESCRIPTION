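Package: leafsignal
Title: Insect-Perceived Leaf Colour, Plant Defence Chemistry and Herbivory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing leaf reflectance spectra through insect
    photoreceptor models and relating the resulting colour channels to plant
    defence chemistry and herbivore presence, preference and performance.
    Builds photoreceptor spectral sensitivities from peak wavelengths with the
    A1 visual-pigment nomogram, computes quantum catches, opponency ratios
    (blue:green, pale-red:green, deep-red:green) and an achromatic brightness
    channel, screens colour-chemistry correlations with false-discovery-rate
    control, fits binomial mixed models of herbivore presence with populations
    nested in counties, and analyses paired-plant choice and performance
    experiments with exact binomial, linear-model and rank-based tests.
    Includes a synthetic-data generator that emulates the survey and
    experiment structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    splines,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
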