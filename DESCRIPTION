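Package: cpdm
Title: Conditional Probabilistic Diffusion Models for Omics-Conditioned
    Medical Image Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits conditional denoising diffusion probabilistic models that
    synthesize 2D grayscale medical-image projections conditioned on
    per-patient multi-omic latent factors. Provides the full workflow:
    orthographic projection and nearest-neighbour resizing of 3D volumes,
    coefficient-of-variation gene filtering, construction and rank-R
    alternating-least-squares CP factorization of a patients x genes x
    modalities omics tensor, a U-Net noise predictor with inner-product
    condition fusion and bottleneck cross-attention, ancestral sampling,
    generative-image evaluation metrics (Frechet distance on image
    embeddings, its batch standard deviation, mean squared error,
    structural similarity), cross-validation fold planning, and a synthetic
    paired image+omics fixture generator for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    RNifti,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
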