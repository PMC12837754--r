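Package: valvesens
Title: Geometric Sensitivity Analysis of Mitral Valve Orifice Area
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for studying how mitral valve geometry controls the
    residual systolic orifice area. Provides a twelve-parameter leaflet and
    annulus parameterization with physiological ranges, a deterministic
    kinematic closure emulator mapping geometry to mid-systole leaflet
    free-edge curves and orifice area, the gap-length cross-sectional
    orifice-area algorithm, Gaussian Process regression with an automatic
    relevance determination kernel plus a linear baseline, first-order
    Sobol sensitivity indices computed by a dimension-fixing Monte Carlo
    scheme, and total-variation comparison of orifice-area distributions.
    User-facing functions take data frames and return tibbles so analyses
    compose with the pipe.
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
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
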