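Package: pyroerr
Title: Error Profiling for 454 GS-FLX Titanium Control-Fragment Reads
Version: 0.1.0
Authors@R:
    person("pyroerr", "maintainers", email = "pyroerr@example.org", role = c("aut", "cre"))
Description: Tools for characterizing per-base error in 454 GS-FLX Titanium
    pyrosequencing using spiked-in control DNA fragments: a read simulator
    with covariate-driven insertion/deletion/mismatch/ambiguous errors and a
    truth log, reference-side homopolymer coding, semi-global affine-gap
    alignment with per-position error calling, Table-style accuracy and
    quality summaries with binomial confidence intervals, balanced
    error/non-error covariate tables, per-plate logistic error models with a
    three-term deviance decomposition and permutation correlation tests,
    sliding-window spatial error maps over PicoTiterPlate coordinates, and
    binomial consensus-coverage calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
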