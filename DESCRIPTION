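Package: petkinetics
Title: Tumor Response Kinetics from Serial FDG-PET/CT Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the decline of quantitative FDG-PET/CT biomarkers (SUVmax,
    metabolic tumor volume, total lesion glycolysis) during induction
    chemotherapy with a shared mono-exponential decay model with an asymptotic
    offset and patient-specific scale factors, fitted by separable nonlinear
    least squares. Provides endpoint-specific backdating of pre-treatment
    scans, standardized-residual classification of poor treatment response,
    leave-one-out cross-validation of the risk flag, exact and rank-based
    association statistics, progression-free-survival analysis, and a
    synthetic-cohort generator with full ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
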