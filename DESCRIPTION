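Package: ihcquant
Title: Automated Immunohistochemical Cell Quantification and Cohort Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative workflow for immunohistochemical profiling of the
    tumor microenvironment in melanocytic lesions. Detects and counts
    positively stained cells in brightfield field images (stain separation by
    color deconvolution, melanin pigment rejection, morphology and intensity
    exclusion rules), aggregates per-field counts with the hotspot method,
    applies semi-quantitative tumor-cell scoring, and runs the downstream
    cohort statistics (Kruskal-Wallis with Dunn post-hoc comparisons, Pearson
    chi-square association tests, Mann-Whitney U, Kaplan-Meier/log-rank and
    Cox regression survival analyses, rater concordance). Includes a
    ground-truthed synthetic image and cohort generator so the whole pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    survival,
    jsonlite,
    stats,
    grDevices,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
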