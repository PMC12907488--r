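Package: ventriseg
Title: Cascaded Detection and Segmentation for Ventricular CSF Volumetry on Head CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic two-stage pipeline for detecting, segmenting and
    volumetrizing twelve ventricular subregions on head computed tomography.
    Axial slices of a standardized 1 mm isotropic 256-cubed CSF-windowed volume
    are passed through per-slice object detection, invertible region-of-interest
    cropping, per-subregion 2D encoder-decoder (U-Net) semantic segmentation,
    and backsampling into a fused 3D label volume from which subregion and
    grouped volumes in ml and relative volumetric errors are reported. Includes
    DICOM/NIfTI/YOLO-format I/O, a seeded synthetic head-phantom generator with
    analytically known subregion volumes, CPU-trainable desk-scale detector and
    U-Net models, and a full evaluation suite (Dice, Jaccard, 95th-percentile
    Hausdorff distance, precision/recall/mAP50/mAP50-95) backed by brute-force
    oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
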