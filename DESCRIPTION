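Package: erodyn
Title: Simulated Erosion-Thickness Plot Design and Soil Nitrogen Dynamics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for designing and analysing simulated soil-erosion thickness
    experiments on cultivated slopes. Implements the tillage-erosion mixing model
    of the cultivated horizon (closed form and year-by-year simulator), the
    cut-and-fill block geometry used to construct erosion plots, a synthetic
    generator for the study-shaped dataset (soil and plant variables plus AMF
    and nifH genus abundance tables over seasons and treatments), and the full
    statistical chain: normality and homogeneity screens, one-way ANOVA with
    Fisher LSD compact letter displays, mineral-nitrogen reduction rates and
    nitrate:ammonium ratios, Bray-Curtis and unweighted UniFrac distances,
    non-metric multidimensional scaling, overall and pairwise PERMANOVA, Shannon
    diversity, and partial-least-squares path modelling with nonparametric
    bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    jsonlite,
    withr
Config/testthat/edition: 3
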