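Package: skimspect
Title: Repeat Spectra, Genome Length and Coverage from Low-Coverage Genome Skims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a genome's k-mer repeat spectrum, length, sequencing
    coverage and error rate from the k-mer count histogram of a low-coverage
    genome skim. The observed histogram is modelled as a Poisson mixture over
    genomic copy-number classes; the ill-conditioned inversion is stabilised by
    ratio constraints learned from assemblies, solved by linear programming,
    and refined with gamma-family smoothing splines of consecutive spectral
    ratios. An outer simulated-annealing loop searches over k-mer coverage.
    Also provides exact canonical k-mer counting, assembly-side repeat
    statistics (uniqueness ratio, high-copy repeats per million, an analytic
    random-genome null bound), and a synthetic genome and shotgun-read
    simulator used for training and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    pracma,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
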