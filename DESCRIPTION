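Package: ivimopt
Title: Optimal b-Value Schemes for Segmented IVIM Modelling of Diffusion MRI
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and evaluation of diffusion-MRI b-value acquisition schemes
    for the intravoxel incoherent motion (IVIM) biexponential model. Simulates
    magnitude (Rician) diffusion signal decays across perfusion regimes and
    noise levels, fits them with the segmented two-step procedure (log-linear
    diffusion fit, intercept-derived perfusion fraction, bounded nonlinear
    pseudo-diffusion fit), scores candidate schemes by the total relative error
    of the recovered parameters, and optimizes schemes by greedy forward
    selection with frequency aggregation and backward elimination. Also
    provides voxelwise IVIM parametric mapping of 4D diffusion-weighted
    volumes, a synthetic digital brain phantom, and NIfTI/FSL-style file
    interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
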