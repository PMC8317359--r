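Package: radlvsi
Title: PET Radiomics and Immunohistochemistry Models of Lymphovascular
    Space Invasion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for predicting lymphovascular space
    invasion (LVSI) in early-stage cervical squamous cell carcinoma from
    FDG-PET radiomics and immunohistochemistry.  Provides fixed-threshold
    (42% SUVmax) tumour segmentation, a 401-feature radiomics catalogue
    (conventional, histogram, grey-level co-occurrence, run-length,
    zone-size and form-factor families), LASSO-based radiomics score
    construction including a published 16-coefficient model,
    DensitoQuant-style H-score quantification of DAB/hematoxylin stains,
    cohort eligibility filtering with a seeded 7:3 split, logistic models
    evaluated by ROC analysis with DeLong comparisons, two-reader
    intraclass correlation, and a seeded synthetic-data generator so the
    whole analysis is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    graphics,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
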