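Package: chromashift
Title: Calibrated Region Colorimetry and Mixed-Model Inference for Body-Colour Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies body-colour plasticity from masked photographs of
    individual animals. Extracts mean CIELAB lightness, hue and chroma over a
    binary mask region after chart-based linear colour calibration, assembles
    per-individual colour shifts between repeated time points, and fits linear
    mixed-effects models with AIC-based model selection, backward
    simplification, random-effect likelihood-ratio tests and estimated
    marginal-mean post hoc comparisons. Includes a synthetic-data module that
    renders fish-on-background fixtures with exact ground-truth region colour
    and simulates phenotype tables for social-context and infection designs,
    supporting parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    png,
    tiff,
    jpeg,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
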