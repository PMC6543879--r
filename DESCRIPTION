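Package: indeldfe
Title: Distribution of Fitness Effects and Linked-Selection Scans for Short
    Insertions and Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood inference of the distribution of fitness
    effects (DFE) for short insertions and deletions from polarized site
    frequency spectra, under a Poisson random field model with ancestral-state
    misidentification (polarization error) and demography nuisance parameters.
    Includes the linear-system correction of orientation errors in unfolded
    spectra, discrete-class and gamma DFE families with AIC model selection,
    estimation of the proportion of adaptive substitutions (alpha), an
    exon-proximity mutation-rate scan, a recombination-window diversity scan
    with partial rank correlations, and a synthetic-data generator with known
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    data.table,
    vcfR,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
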