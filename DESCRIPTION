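Package: divmap
Title: Divergence-Based Localization of Focal Activation Sources from
    Multielectrode Mapping
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs continuous cardiac activation maps from scattered
    multielectrode activation times by polyharmonic (Duchon cubic) radial
    basis function interpolation, derives conduction-velocity vector fields
    analytically from the interpolant, and localizes focal activation
    sources as maxima of the divergence of the normalized velocity field.
    Includes multipolar catheter layout generators, a tissue-patch
    activation-pattern simulator (plane wave, focal source in homogeneous
    and heterogeneous tissue, wavefront collision) with an eikonal
    fast-marching backend, corruption models (activation-time jitter, site
    removal), Monte-Carlo stability experiments, and barycenter-based
    activation-time annotation of bipolar electrograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    mgcv,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
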