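Package: firstsight
Title: Decoding Which of Two Suppressed Images Reaches Awareness First
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether access to visual awareness under
    interocular suppression is predictable from the spatial-frequency and
    orientation contrast energy of the competing images rather than from
    their semantic (e.g. emotional) content. Provides wedge-binned Fourier
    magnitude features (24 spatial-frequency by 16 orientation ranges per
    image), a synthetic stimulus and response generator with controllable
    per-wedge contrast energy, an ensemble feature-selection decoder
    (filter, wrapper, random and pseudo-random SVM models over stratified
    folds with a shuffled-label control pool and regression-to-the-mean
    matched significance thresholds), feature-weight correlation analyses,
    and behavioral statistics for two-alternative first-percept data
    (Friedman and Wilcoxon signed-rank tests, and cross-validated
    bias-based prediction with a permutation test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
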