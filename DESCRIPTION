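Package: plateaugap
Title: Three-Dimensional Gap Area Quantification for Tibial Plateau Fractures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies initial and residual articular displacement of
    tibial plateau fractures from labeled fragment surface meshes using the
    3D gap area: the summed area (mm^2) of a triangulated surface spanning
    the fracture lines extracted from the articular surface. Includes rigid
    surface-based matching (trimmed point-to-plane ICP) of preoperative
    fragments to a postoperative model for residual displacement,
    radiographic reduction parameters (articular gap/step-off, MPTA, PPTA),
    KOOS questionnaire scoring with total-knee-arthroplasty imputation,
    prognostic stratification by gap area, and confounder-adjusted linear
    regression of patient-reported outcome on displacement. A synthetic-data
    module generates fractured plateau meshes with analytic and numeric
    gap-area oracles and simulated patient cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    grDevices,
    jsonlite,
    RANN,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
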