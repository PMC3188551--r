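Package: facesom
Title: Hierarchical Self-Organising Map Model of Face Identity and
    Expression Separation in the Ventral Visual Stream
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a rate-coded model of the primate ventral visual
    pathway built from a feedforward hierarchy of four self-organising
    maps (SOMs) with Hebbian learning, together with the full experiment
    in which the model is trained on a parametric set of 1600 cartoon
    faces (40 identities x 40 expressions) and develops spatially
    clustered output neurons selective for either facial identity or
    facial expression. Provides the deterministic cartoon-face stimulus
    generator, a V1-like oriented difference-of-Gaussians filter bank,
    topological sparse connectivity, Mexican-hat lateral competition,
    percentile-threshold sigmoid firing, layer-wise training, firing-rate
    response analyses (response matrices, isolated-space tuning curves,
    cell typing, spatial clustering statistics) and the quantised
    single-cell stimulus-specific information analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
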