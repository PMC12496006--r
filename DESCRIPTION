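Package: lcscreen
Title: Lung Cancer Screening Natural-History Microsimulation and Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Microsimulation of lung-cancer natural history and low-dose CT
    screening trials in the style of the NELSON (Dutch-Belgian) randomized
    trial. Individual life histories combine a two-stage clonal expansion
    (TSCE) carcinogenesis model driven by cigarette smoking, Weibull
    preclinical sojourn times through TNM stages IA-IV by histology, clinical
    detection, mixture-cure post-diagnosis survival, and smoking-adjusted
    other-cause mortality. A four-round CT protocol with stage- and
    histology-specific sensitivity and stage-specific mortality-prevention
    (cure) probabilities is applied to a synthetic high-risk cohort generator,
    so the whole pipeline runs without restricted trial microdata. Model
    parameters are calibrated to trial-style count targets by differential
    evolution against a composite Poisson/multinomial likelihood, with
    profile-likelihood feasible ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
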