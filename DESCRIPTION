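Package: ParBcycle
Title: Nonequilibrium Kinetics of ParB Sliding-Clamp Loading and Spreading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Models the CTP-dependent ParB clamp cycle that concentrates the
        bacterial partition protein ParB at centromeric parS sites. Provides
        the analytic steady-state solution of the coarse open/closed clamp
        network and its observed ("ultra-affinity") dissociation constant,
        an exact stochastic simulator (direct method) for the coarse and
        nucleotide-resolved reaction schemes, a one-dimensional lattice
        simulator of clamp loading, diffusive spreading and
        hydrolysis-driven unloading that produces ChIP-like occupancy
        tracks, and quantitative models with fitters for the standard
        in-vitro readouts: ITC binding isotherms, BLI dissociation and
        CTP-dependent retention, and CTPase phosphate-release rates.
        Synthetic-data generators with embedded ground truth support
        recovery testing of every fitter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    yaml,
    Rcpp,
    S4Vectors,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
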