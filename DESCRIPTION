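Package: pasa
Title: Sparse Mutational Signature Attribution by Likelihood Ratio Tests
Version: 0.9.0
Authors@R: person("Maintainer", "Packageauthor", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Attribution of mutational signature activities to SBS, DBS and
    indel mutational spectra using a two-step likelihood-ratio-test driven
    algorithm (signature presence filtering followed by greedy forward
    selection under a negative binomial count model), together with a
    non-negative least squares baseline, a negative-binomial synthetic
    spectrum generator with dispersion calibration, benchmarking metrics
    (precision, recall, scaled Manhattan distance, Combined Score, KL
    divergence), and exhaustive enumeration of alternative attributions to
    quantify attribution ambiguity.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
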