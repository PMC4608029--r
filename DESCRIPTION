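Package: minicircle
Title: Tracing and Topological Analysis of Supercoiled DNA Minicircles in Cryo-ET Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the three-dimensional conformations of small
    covalently closed DNA circles (minicircles) imaged by electron
    cryo-tomography. Generates synthetic tube-density phantoms for the seven
    empirical minicircle shape classes (open circle, open figure-8, figure-8,
    racquet, handcuffs, needle, rod), traces closed DNA backbones in density
    volumes with an iterative closed-polygon snake (5 to 10 to 20 vertices,
    density/edge-length/angle score, multi-start convergence checks), and
    computes topological and shape statistics: writhe by the Gauss double
    integral, linking-number bookkeeping (Lk, Lk0, dLk, superhelical density),
    crossover sign analysis, density-weighted radius of gyration, principal
    axis lengths and ellipticity, rule-based shape classification, population
    shape distributions with a weighted compactness score, and circular
    restriction-fragment mapping of nuclease cleavage sites. Reads and writes
    MRC density volumes and plain-text trace tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
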