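Package: iansegmap
Title: Intraosseous Localization and Morphometry of the Inferior Alveolar Nerve
    on Paired MRI and CBCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for localizing the inferior alveolar nerve (IAN) within the
    inferior alveolar canal (IAC) on coronal reference images. Implements the
    landmark-based six-segment partition of the canal cross-section, per-segment
    hyperintensity occupancy scoring with an inclusive half-area visibility
    rule, marginal and conditional occupancy tables, seeded region-growing
    segmentation of canal and nerve with maximum Feret-diameter morphometry in
    the axial, sagittal and coronal planes, and cross-modality (CBCT/MRI)
    conversion-factor statistics with a one-sample Wilcoxon signed-rank design.
    A synthetic phantom generator produces paired CBCT-like and MRI-like
    volumes with fully known ground truth so that every pipeline stage can be
    validated against analytic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
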