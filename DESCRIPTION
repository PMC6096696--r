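Package: macchia
Title: Distinctiveness of Pointillist Colour Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how distinct two pointillist colour fields look
    across a shared transition. Generates bipartite pointillist stimuli (Voronoi
    dot layouts with hard or soft edges and achromatic, monochromatic or
    polychromatic colour gamuts), decomposes cardinal-colour pairs into
    per-channel transitions and veils, simulates synthetic observers that set a
    matching achromatic Michelson contrast, and runs the analysis chain:
    observer normalisation, Kendall-tau concordance, pair summaries and array
    matrices, and a three-way comparison of CIE luminance contrast, CIEDE2000
    and raw RGB-cube distance as predictors of distinctiveness, including a
    Monte-Carlo probe of CIEDE2000 triangle-inequality violations.
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
    grDevices,
    tools,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
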