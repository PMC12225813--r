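Package: mbnav
Title: Bilateral Mushroom-Body Memory Model of Insect View-Based Navigation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates view-based navigation in a cylindrical arena with a
    bilateral Mushroom-Body memory model. Renders panoramic greyscale views of
    wall shapes from arbitrary agent poses, splits views into overlapping left
    and right visual fields, and trains lateralised left/right Kenyon-cell
    memory networks with an anti-Hebbian depreciation rule along a feeder-bound
    path. Rotational novelty signals (left, right, sum, difference) are turned
    into simulated saccade-endpoint heading distributions by a rejection
    sampler, pooled across crossover/overlap parameter grids, and scored by
    kernel-density modes. A numerical theory oracle verifies why balancing
    left and right novelties encodes the fractional position of mass (FPM) of
    a trained shape.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
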