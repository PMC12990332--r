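Package: morphoscreen
Title: Morphometric Quality-Control Screening of Brain Organoids from
    Brightfield Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated quality-control screening of neural organoids
    from calibrated 2D brightfield images. Segments one organoid per image,
    extracts a 16-descriptor morphometric profile covering size, shape,
    surface complexity (signed contour curvature, inflection points,
    Dirichlet normal energy) and texture (Laplacian-of-Gaussian response),
    embeds samples in a scaled-PCA morphospace, and co-clusters input
    organoids with a curated reference pool (k-means on the principal
    components retaining >90% of the variance) to produce an unbiased
    retain/discard decision per organoid. Includes a parametric generator
    of organoid-like shapes and rendered brightfield-style images with
    closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
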