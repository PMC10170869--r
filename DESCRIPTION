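Package: fibroct
Title: Micro-CT Quantification of Murine Lung Fibrosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of lung fibrosis progression from
    respiratory-gated micro-CT of the murine thorax. Reads paired
    end-inspiration/end-expiration Hounsfield-unit volumes with labeled
    left/right lung masks (NIfTI), computes per-lobe densitometric
    parameters (lung volume, mean lung attenuation, air volume, functional
    residual capacity) and derived morphological and functional biomarkers
    (normo-/hypo-/non-aerated compartments, tissue volume, percent gas,
    tidal volume), runs the longitudinal group statistics used in
    bleomycin-model drug studies (control normalization, two-way ANOVA with
    Dunnett and Sidak post-hoc contrasts, paired left-versus-right lobe
    tests, percent inhibition/recovery), and correlates imaging biomarkers
    with Ashcroft histology scores. Includes a synthetic paired-phase
    thorax phantom generator with exact per-voxel ground truth so the whole
    pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
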