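Package: perfusim
Title: Dual-Modality Cerebral Perfusion Simulation and Analysis for
    Ischemia-Reperfusion Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses cerebral perfusion imaging of transient
    middle cerebral artery occlusion (tMCAO) in the rat across two modalities:
    ultrafast-ultrasound power Doppler (relative cerebral blood volume via
    singular-value-decomposition clutter filtering), ultrasound localization
    microscopy (blood flow velocity from tracked microbubbles), and dynamic
    susceptibility contrast MRI (CBV by truncated integration of the tissue
    concentration curve, CBF by block-circulant SVD deconvolution against an
    arterial reference, T2 relaxometry for lesion delineation). A digital
    ischemia-reperfusion phantom with recorded ground truth supports
    parameter-recovery validation of the full processing chain, including
    region-of-interest time courses, normalized ipsi/contralesional ratios,
    recanalization intercept mapping, and cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr,
    yaml
Config/testthat/edition: 3
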