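Package: circoast
Title: Colocalization of Disk-Shaped Cells with Network Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical hypothesis tests for whether disk-shaped objects
    (cells, vesicles, microspheres) colocalize with a network structure
    (microvasculature, neurites, cytoskeleton) in 2D images more often than
    random placement predicts, independent of cell and network density. The
    cell-dilated network fraction (CDNF) of an image gives the exact success
    probability of a binomial null model of random placement; upper-tail
    binomial tests per image are pooled across images, combined across
    biological replicates against a simulated pseudo-null of mean uniform
    p-values, and compared between study groups by permutation. Includes a
    Monte Carlo random-placement simulator, a hypergeometric finite-packing
    variant with a Monte Carlo packing-ratio estimator, a synthetic
    vessel-network generator (minimum-distance point cloud, watershed
    bisection, iterative segment pruning), and scripted in-silico validation
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
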