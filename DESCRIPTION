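Package: mambaseg
Title: Lightweight State-Space U-Net for Brain MRI Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a lightweight encoder-decoder network for binary lesion
    segmentation of multi-modal brain MRI. The encoder stacks mobile inverted
    bottleneck (MBConv) convolutions; every stage is refined by visual
    state-space (VSS) blocks whose core is a four-directional 2D selective-scan
    linear state-space recurrence; spatial and channel attention bridges gate
    the bottleneck and decoder; a U-Net style decoder with patch expansion
    restores full resolution. Training minimises a hybrid of Active Contour
    Loss and Focal Loss with AdamW and cosine annealing. The package ships a
    seeded synthetic multi-modal volume generator, a NIfTI preprocessing
    pipeline (per-volume intensity normalisation, modality stacking, axial
    slicing, lesion-slice filtering, resizing, augmentation), the full
    surface-distance evaluation suite (DSC, precision, recall, F1, mIoU, ASSD,
    Hausdorff distance) and a command-line interface. All numerical kernels
    (convolutions, state-space scans and their gradients) are implemented in
    C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
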