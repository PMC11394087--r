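Package: crocdiet
Title: Stomach-Content Diet Composition Analysis for Crocodilian Hatchlings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of stomach-content (diet) data for size-classed
    animals, developed around hatchling Morelet's crocodile diet studies. Computes
    numeric, volumetric and frequency-of-occurrence percentages, the relative
    importance index (RII) with low/secondary/high classification, Simpson dietary
    diversity with a stomach-bootstrap comparison test, Pianka niche overlap between
    size classes, a bootstrap chi-square goodness-of-fit test with standardized
    residuals, and per-item logistic regression of prey presence against total body
    length. Includes a synthetic stomach-content generator, an integer-count
    reconstruction utility for tables that print only rounded percentages, and a
    reconstructed example dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), vegan, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
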