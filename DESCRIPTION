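Package: deepvasc
Title: Restoration and 3D Vascular Morphometry for Deep Fluorescence
    Microscopy Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Restores deep three-photon fluorescence z-stacks corrupted by
    line-wise stripe noise and photon-limited random noise, then quantifies
    the imaged vasculature. Stripe noise is removed frame-wise by a low-rank
    singular value decomposition filter gated on the ratio of the two
    leading singular values; random noise is removed by a self-supervised
    denoising diffusion model whose U-Net noise predictor is trained on the
    shallow (high-quality) side of the stack. Includes a synthetic vessel
    phantom generator with a realistic degradation model (depth attenuation,
    scattering background, stripes, shot and readout noise), image quality
    metrics (SBR, SSIM, PSNR, MSE, F1), voxel-wise 3D vascular morphometry
    (volume density, thickness, skeleton density, complexity, surface-area
    index), and a linear support vector machine classifier that maps
    morphometric feature vectors to brain-region labels with region-boundary
    depth estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
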