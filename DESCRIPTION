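Package: t1rhomap
Title: Accelerated Mono- and Biexponential T1rho Mapping of Knee Cartilage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for accelerated quantitative T1rho relaxometry of knee
    cartilage from undersampled multi-coil Cartesian MRI. Provides the
    multi-coil Fourier acquisition operator with coil-sensitivity and
    low-order phase estimation, 2D+time Poisson-disk undersampling masks
    with a fully sampled calibration region, l1-regularized compressed
    sensing reconstruction with spatial and spatio-temporal finite
    difference transforms, an unrolled variational network reconstruction
    with learned filters, activations and step sizes, complex-valued mono-
    and biexponential relaxation fitting with F-test model selection, a
    synthetic phantom generator with known ground truth, and the error and
    repeatability metrics (nRMSE, NAD/MNAD, ROI statistics, CV, ANOVA)
    used to evaluate accelerated parametric mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
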