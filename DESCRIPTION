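Package: facedim
Title: Facial Sexual Dimorphism in Shape and Color
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies sexual dimorphism of human faces in shape and in skin
    color. Shape dimorphism (SShD) is scored from two-dimensional landmark
    configurations: faces are symmetrized, jointly aligned by Generalized
    Procrustes Analysis, and projected onto the axis joining the female-mean
    and male-mean shapes. Color dimorphism (SCoD) is scored analogously from
    CIELAB skin measurements and adapted Michelson contrasts between facial
    features (eyes, brows, lips) and surrounding skin. Inference uses a
    permutation test on the Euclidean distance between sex-specific means,
    with Cohen's d effect sizes, per-channel one-way ANOVA, Pearson
    correlations with perceived attractiveness, and ICC(3,k) inter-rater
    reliability. Includes a synthetic-population generator with known
    dimorphism parameters for validation, readers and writers for TPS
    landmark files, and sRGB to CIELAB conversion for image-based region
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
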