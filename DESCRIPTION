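Package: wlcbuckle
Title: Exact Buckling Statistics of Fluctuating Worm-Like Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical mechanics of buckling for a semiflexible polymer under
    compressive load. Computes the exact end-to-end distance distribution of the
    worm-like chain from the continued-fraction representation of its
    Fourier-Laplace Green function (pole/residue and numerical contour
    inversions), assembles compressive free-energy landscapes
    F/kBT = -log(R^2 G) + f R, extracts fluctuation-renormalized critical
    buckling forces from the response function -dRmin/df, provides the
    zero-temperature Euler elastica reference (elliptic-integral
    force-extension and constrained bending energy), and includes a seeded
    Metropolis Monte Carlo simulator of the bead-discretized chain in
    fixed-extension and fixed-force ensembles with energy/entropy
    decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
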