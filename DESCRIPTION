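Package: surfsearch
Title: Bayesian-Optimization Structure Search for Rigid Adsorbates on
    fcc(111) Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Active-learning identification of stable adsorbate structures of
    a rigid molecule on a close-packed metal surface. A Gaussian-process
    surrogate of the potential energy surface is built over rigid-body pose
    coordinates (two fractional surface translations, an adsorption height and
    three rotation angles) with per-dimension periodic kernels, refined
    iteratively with the exploratory lower-confidence-bound acquisition
    function, and data-mined for all its minima with multistart L-BFGS.
    Translation barriers are estimated with a climbing-image nudged elastic
    band on the surrogate and rotation barriers with one-dimensional in-place
    searches. The package also builds orthogonal-cell fcc(111) slab models,
    augments datasets with the surface's twofold translational and threefold
    rotational symmetries, and reproduces the bookkeeping arithmetic used to
    report adsorption energetics, partial-charge sums and hindered-rotation
    occupancies. Analytic adsorption-like energy surfaces are bundled so the
    whole workflow runs and is tested without an electronic-structure code.
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
    lhs,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
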