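Package: retsuperpix
Title: Red Lesion Detection in Fundus Images by Entropy Rate Superpixel
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects red lesions (microaneurysms and hemorrhages), the
    earliest signs of diabetic retinopathy, in color fundus photographs.
    The pipeline normalizes image appearance (field-of-view extraction,
    bright border artifact removal, background extension, illumination
    and color equalization, denoising, contrast-limited adaptive
    histogram equalization), computes a multiscale darkness map, groups
    pixels into superpixels by greedy entropy-rate graph clustering,
    reduces and merges superpixel candidates, extracts 39 shape,
    intensity, edge, line-operator and landmark-distance features per
    candidate, selects features with the fast correlation-based filter,
    and classifies candidates with a regularized multilayer perceptron.
    Includes a synthetic fundus scene generator with exact ground truth
    for training and evaluation, plus pixel-level and image-level
    performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
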