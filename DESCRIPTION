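Package: mdprops
Title: Property Extraction from Molecular Dynamics Outputs of Amorphous Polymers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for molecular dynamics outputs of
    amorphous polymer systems such as cellulose derivatives. Reads
    engine-style tabular output (xvg-like) and coordinate frames (GRO,
    extended XYZ), and computes glass-transition temperatures by
    broken-stick regression on specific-volume-temperature curves,
    volumetric thermal expansion coefficients, hydrogen-bond kinetics via
    the intermittent existence function with bi-exponential decay
    extrapolation (lifetimes and half-lives), tensile and elastic
    constants (Young's modulus, maximum stress, Poisson's ratio, bulk
    modulus) from deformation series, probe-insertion free-volume
    fractions of periodic configurations, and Einstein-relation
    diffusivities from mean-square displacements with a split-half error
    estimate. A synthetic-data module generates every input class with
    known ground truth so each analysis is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
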