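Package: icvsampler
Title: Protocol Evaluation for Intracranial Volume Estimation by Slice
    Subsampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for designing and evaluating intracranial volume (ICV)
    estimation protocols. Provides a synthetic cranial-cavity phantom
    generator with controllable surface roughness, voxel-count volumetry,
    the interleaved slice-subsampling (Cavalieri) ICV estimator, a
    randomized reliability analysis based on empirical distributions of
    the two-way random-effects intraclass correlation coefficient,
    extraction of maximum-safe-sampling-period guidelines, and an
    agreement battery (paired t-tests, Pearson correlation, mean related
    percentage of absolute difference, factorial general linear model)
    for comparing manual operators and automated volumetry tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
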