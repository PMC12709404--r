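Package: trivesicle
Title: Dynamically Triangulated Vesicle Simulations with Internal Active Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Langevin-dynamics simulator for fluid, dynamically triangulated
    membrane vesicles with constrained area and volume that enclose
    self-propelled semiflexible bead-spring filaments.  Implements Helfrich
    curvature elasticity on a triangle mesh (cotangent Laplacian with Meyer
    mixed areas), harmonic area/volume constraints, two-part tether bond
    potentials, membrane self-avoidance, Metropolis bond-flip moves for
    membrane fluidity, and an underdamped Langevin integrator.  Ships a
    shape-analysis toolkit: membrane asymmetry, analytic capped-cylinder tube
    and toroidal sheet reference models, a shape index for classifying cups,
    sheets, tubes, branched tubes and pearled tubes, skeleton-based counting
    of tubular junctions with emergence/retraction turnover rates, and a
    virial estimator of membrane tension.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
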