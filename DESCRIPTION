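Package: OrthoCBCT
Title: Synthetic CBCT Volumes from Orthogonal Projections and a Planning CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synthesizes volumetric cone-beam CT (CBCT) images for
    image-guided prostate radiotherapy from two orthogonal 2D projections
    (digitally reconstructed radiographs at gantry angles 0 and 270 degrees)
    plus the patient's planning CT. Provides an anthropomorphic pelvic
    phantom simulator with inter-fractional bladder and rectal-gas variation,
    NIfTI preprocessing (intensity truncation, min-max normalization, central
    cropping, paired augmentation, unified structure masks), parallel-beam
    DRR rendering as a differentiable operator, a dual-branch
    encoder-decoder network family (fusion, skip, residual variants) built
    on a compact reverse-mode autodiff core with C++ convolution kernels, an
    anatomically informed multi-component loss (voxel MAE, 2.5D perceptual
    loss, DRR-consistency loss, structure-masked loss), an AdamW training
    protocol with plateau learning-rate decay and best-checkpoint selection,
    masked image-quality metrics (mMAE, mSSIM, mPSNR, cLPIPS) and a
    Kruskal-Wallis/Dunn statistical comparison harness for loss ablations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
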