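Package: histotex
Title: Texture and Texture-Derivative Analysis of Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies treatment-induced changes in tumour cellular
    architecture from H&E histology images using four gray-level texture
    matrix families (GLCM, GLSZM, GLDM, NGTDM; 59 features), windowed
    texture maps with median summaries, and second-pass texture-derivative
    features computed on those maps. Also provides semi-quantitative
    DCE-MRI perfusion analysis (initial AUC, muscle normalisation, maximum
    intensity projection) and tertile-based perfusion-targeted treatment
    cell masking, a synthetic phantom generator for histology textures and
    DCE signal curves, and group statistics (one-way ANOVA with Bonferroni
    pairwise post hoc tests). Tabular results are returned as tibbles so
    analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    png,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
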