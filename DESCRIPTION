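Package: cbecea
Title: Markov Cohort Cost-Effectiveness Model of Clinical Breast
    Examination Screening in HER2-Positive Breast Cancer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A six-state monthly-cycle Markov cohort model comparing a
    clinical-breast-examination (CBE) screening scenario against no
    screening for HER2-positive breast cancer patients. The model tracks
    disease-free survival on and off treatment, non-metastatic
    recurrence, remission, metastatic disease and death over a lifetime
    horizon with tunnel states for time-in-state mortality, half-cycle
    correction and 1.5% annual discounting. It produces life-years,
    quality-adjusted life-years and costs from the patient, public-payer
    and healthcare-sector perspectives, incremental cost-effectiveness
    ratios against WHO willingness-to-pay thresholds, one-way
    deterministic (tornado) sensitivity analysis and probabilistic
    sensitivity analysis with cost-effectiveness plane and acceptability
    curve outputs. Includes synthetic fixture generators (life table,
    censored disease-free-survival event data), parametric survival
    curve fitting with a cure fraction, and a microsimulation oracle for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    MASS,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
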