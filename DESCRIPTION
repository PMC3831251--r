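Package: epiclass
Title: Antibody Class-Specific B-Cell Epitope Prediction from Peptide Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts whether a linear B-cell epitope is likely to induce an
    IgG, IgE or IgA antibody response from its amino-acid sequence. Provides
    six peptide feature encodings (amino-acid composition, dipeptide
    composition, binary profiles, physico-chemical property means,
    composition-transition-distribution descriptors and an amino-acid-pair
    propensity scale), one-vs-rest dataset construction with balancing and
    fixed-length normalisation, support-vector-machine training and tuning,
    threshold-dependent evaluation (sensitivity, specificity, accuracy,
    Matthews correlation coefficient) and ROC/AUC, sliding-window antigen
    scanning, exact epitope mapping and Smith-Waterman similarity search, plus
    class-wise composition analysis and a seeded synthetic peptide generator
    for offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
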