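Package: wfpn
Title: Weighted Feature Pyramid Networks for Pressure-Injury Image Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a weighted feature pyramid network (wFPN) for
    fine-grained classification of pressure-injury images into NPUAP
    stages 1-4. The architecture combines a top-down and a bottom-up
    feature-fusion pathway with fast-normalized learnable fusion weights,
    convolutional block attention (CBAM) on every top-down level, and a
    weighted ensemble of per-level classifiers. Ships a self-contained
    reverse-mode autograd engine (convolution, pooling, attention gates,
    AdamW, cosine annealing), a stratified splitter, the full multiclass
    evaluation stack (confusion matrix, precision/recall/F1, macro-F1,
    one-vs-rest ROC/AUC), a deterministic synthetic skin-lesion image
    generator with controllable class separability, and a command-line
    interface, so the method can be trained and evaluated end-to-end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    jpeg,
    png,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
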