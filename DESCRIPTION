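Package: ielquant
Title: Digital Quantification of Intraepithelial Lymphocytes and the
    Subepithelial Band in Intestinal Mucosa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reproducible pipeline for CD3 immunohistochemistry
    quantification in colonic and ileal biopsies: synthetic stained-histology
    generation with pixel-level ground truth, H-DAB colour deconvolution,
    four-class tissue compartment segmentation, nucleus detection with
    CD3-positivity calling, per-compartment metrics (intraepithelial
    lymphocytes per 100 epithelial cells, lamina propria CD3+ density per
    square millimetre, subepithelial band thickness in micrometres),
    microscopic-colitis diagnostic classification, and the accompanying
    comparison statistics (paired t-test, exact Wilcoxon-Pratt signed-rank
    test, Bonferroni correction, ordinal frequency tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    EBImage,
    ranger
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
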