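Package: ecgscar
Title: Explainable ECG-Based Detection and Localization of Left Ventricular Scar
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts the presence of left-ventricular scar in the basal, mid,
    and apical LV regions from fiducial-annotated 12-lead electrocardiograms,
    and explains every prediction with per-feature Shapley scores. The pipeline
    extracts 23 depolarization/repolarization features per lead (276 per ECG),
    removes confounding by LV mass index, age and sex via multiple linear
    regression during training, recursively partitions patients into merged
    groups with a Dirichlet-process Gaussian mixture and a decaying
    class-dominance rule, trains a contrastive self-supervised encoder with a
    supervised classification head per group and region, and attributes each
    prediction to input features with Kernel SHAP. Ships a synthetic ECG and
    cohort generator with analytically known feature values so the whole
    pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
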