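Package: maskpose
Title: Weakly Supervised 6D Pose Estimation of Rigid Instruments from
    Silhouette Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the 6D pose (rotation and translation) of rigid,
    texture-poor instruments - such as endoscopic surgical tools - from a
    single binary foreground mask. Provides synthetic silhouette training
    data generation from triangle meshes (uniform SE(3) pose sampling,
    software rasterization, farthest-point keypoint selection, Gaussian
    heatmap ground truth, noise augmentation), a multi-resolution
    convolutional heatmap network with channel-space tensor self-attention
    trained by a staged composite objective, a back-propagatable
    Perspective-n-Point layer whose backward pass follows the implicit
    function theorem, a differentiable soft-silhouette rendering loss for
    global contour consistency and gradient-based pose refinement, and the
    standard evaluation metrics ADD, ADD-S, 2D projection error and IOU
    with threshold accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
NeedsCompilation: yes
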