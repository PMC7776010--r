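Package: rdfibre
Title: Orientation-Resolved Relaxation-Diffusion MRI Fibre Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric analysis of 5D relaxation-diffusion correlation MRI.
    Multi-echo, tensor-valued (b-tensor) diffusion signals are inverted per
    voxel into discrete joint distributions of transverse relaxation rate and
    axisymmetric diffusion tensors with a two-cycle (proliferation/mutation)
    Monte-Carlo non-negative least-squares algorithm and bootstrap resampling.
    Distribution components are classified into 'thin'/'thick'/'big' bins,
    fibre-like ('thin') components are mapped to smooth orientation
    distribution functions on electrostatic-repulsion sphere meshes via a
    Watson kernel, and per-peak orientation-resolved means of T2, R2,
    isotropic diffusivity and squared diffusion anisotropy are extracted.
    Includes an in-silico crossing-fibre simulator and evaluation tools, plus
    readers/writers for NIfTI volumes, protocol tables, ensembles and meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
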