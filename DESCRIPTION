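Package: germresp
Title: Germination Response to Temperature and Water Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Characterises seed germination responses to temperature and
    water potential from cumulative germination time courses. Fits Gompertz
    time-course curves, derives percentile germination rates, fits the Yin
    beta-function thermal response to estimate cardinal temperatures
    (minimum, optimum, maximum), estimates base temperature and base water
    potential from the linear phase of the rate response, and classifies
    species into functional germination groups by Ward hierarchical
    clustering. Includes a packaged table of cardinal temperatures for 36
    cover crop taxa, helpers for PEG-8000 osmotic solutions, and a synthetic
    seed-lot experiment generator with known ground truth for validating
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LazyData: false
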