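Package: vasquant
Title: Quantification of Tumor Vasculature, Endothelial Junctions and
    Nuclear Marker Accumulation in Fluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image-quantification and assay-math toolkit for tumor
    vascular biology. Implements a vessel morphometry pipeline
    (histogram equalization, Hessian-based Frangi vesselness, Otsu
    segmentation, morphological thinning, branch-point detection,
    skeleton length and Euclidean-distance-transform diameters, and
    ImageJ-style particle analysis), object-overlap perfusion and
    dextran-leakage indices, DAPI-driven nuclear segmentation with
    per-nucleus marker quantification, VE-cadherin junction length,
    continuity and gap-index metrics, and the accompanying assay
    statistics (tumor volume, 2^-ddCt relative quantities, H-scores,
    standard-curve interpolation, ChIP signal relative to input, 2x2
    Pearson chi-square and Spearman rank correlation). A synthetic
    multi-channel microscopy generator with exact ground truth makes
    every stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
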