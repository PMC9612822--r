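Package: escrtsim
Title: Coarse-Grained Simulation of ESCRT-III-Driven Membrane Remodelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A coarse-grained molecular dynamics simulator of membrane
    remodelling by staged ESCRT-III filament exchange. Implements a
    one-particle-thick fluid membrane with an orientation-dependent pair
    potential, copolymerising spiral and helical filaments whose target
    geometry is encoded in harmonic bond rest lengths, Langevin dynamics in
    the isothermal-isobaric (zero lateral tension) ensemble, staged
    recruitment/constriction/disassembly protocols driving flat-to-buckle,
    buckle-to-tubule and scission transitions, and quantitative observables
    (membrane deformation angle, bending rigidity from the height-fluctuation
    spectrum, pore and scission detection, copolymer stability, subunit
    partitioning).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
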