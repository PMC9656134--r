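Package: epivuln
Title: Composite Vulnerability Indices for District-Level Epidemic Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds composite epidemic-vulnerability indices for small
    administrative areas from socio-economic indicator tables. Implements
    the full pipeline: coefficient-of-variation and collinearity screening
    of indicators, zero-unitarization (min-max normalization with reversal
    of destimulants), Perkal standardized-sums aggregation into a general
    index and nature/relation component indices, four-class delimitation by
    the mean +/- standard deviation rule, temporal Pearson association of
    indices with cumulative incidence panels, p-value-driven stepwise OLS
    refinement of the indicator set, and a latent-factor synthetic district
    generator with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
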