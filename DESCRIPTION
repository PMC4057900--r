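Package: mdevqspr
Title: Topological QSPR Models for Octanol/Air Partitioning of
    Polybrominated Diphenyl Ethers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the molecular distance-edge vector (MDEV) index of
    polybrominated diphenyl ether (PBDE) congeners from their bromine
    substitution pattern and models the base-10 log octanol/air partition
    coefficient (lgKOA) from the descriptor pair (mu1, mu2).  Provides the
    congener nomenclature parser and molecular skeleton graph, ordinary
    least-squares calibration with regression diagnostics, a linear
    artificial neural network trained by SVD pseudo-inverse with a
    verification split, leave-one-out and external validation with percent
    relative errors and RMSRE, a packaged 22-congener study dataset, a
    synthetic congener/response generator for parameter-recovery testing,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
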