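Package: sphfod
Title: Fiber Orientation Distribution Estimation with Equivariant Spherical CNNs
Version: 0.1.0
Authors@R: person("sphfod", "developers", role = c("aut", "cre"),
    email = "sphfod@example.org")
Description: Voxel-wise estimation of white-matter fiber orientation
    distributions (FODs) from reduced multi-shell diffusion MRI using a
    rotationally equivariant spherical convolutional network operating in
    the even-degree spherical-harmonic domain. Includes the real symmetric
    spherical-harmonic toolbox (transforms, sphere samplings, SH-space
    rotation operators), a multi-shell dMRI simulator with planted fiber
    configurations and Rician noise emulating a reduced neonatal protocol
    (19/26/38 directions at b = 400/1000/2600 s/mm^2), a shell-attention
    fusion module, a spatial-domain reconstruction loss, an MLP baseline,
    angular evaluation metrics (ACC, angular error, peak match rate, SSIM,
    PSNR), NIfTI/bval/bvec input-output, and a command-line interface for
    simulate/train/predict/evaluate workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
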