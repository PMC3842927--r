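Package: spermshape
Title: Geometric Morphometrics of Rodent Sperm Head Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics for falciform rodent sperm
    heads. Reads and writes TPS-format landmark files, canonicalizes head
    orientation, performs generalized Procrustes superimposition with
    bending-energy sliding of semilandmarks, computes thin-plate-spline
    deformation grids, derives traditional morphometric descriptors (head
    length, width, area, perimeter, ellipticity, elongation, regularity,
    roughness), and implements a three-step protocol that standardizes
    Procrustes shape coordinates on a traditional variable by multivariate
    regression and tests residual species differences with permutation-based
    Procrustes distances and Procrustes ANOVA. Includes a synthetic sperm-head
    generator so the full pipeline is testable without micrographs.
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
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
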