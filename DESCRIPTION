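Package: nucleowrap
Title: Nucleosome DNA Unwrapping, Contact, and Assembly Geometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structural analysis of nucleosome-like assemblies: counting
    terminally unwrapped DNA base pairs with a heavy-atom minimum-distance
    rule, per-residue histone-DNA and histone-histone contact profiles with
    region totals and copy/replica averaging, native-contact fractions
    (q factor) for assembly progress, trajectory geometry (RMSD after
    least-squares superposition, end-to-end distances, radius of gyration,
    per-residue RMSF, three-point linker-DNA angles), and histogram peak
    summaries of distance distributions.  Includes a synthetic generator of
    idealized wrapped nucleosome core particles, peeled/unwrapped states,
    stochastic two-state DNA-breathing trajectories, and chromatosomes with
    articulated linker-DNA arms, providing ground-truth-labeled inputs for
    validating the analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
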