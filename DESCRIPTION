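Package: saadyn
Title: Population Dynamics of an X-Linked Sexually Antagonistic Allele
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-time population-genetic model of an X-linked sexually
    antagonistic allele in discrete-generation Drosophila cage populations:
    Mendelian X-linked transmission, a photoperiod-weighted male mating
    advantage, genotype-specific female fecundity costs, deterministic
    genotype-frequency recursion with equilibrium analysis, a stochastic
    300-offspring sampling variant with ensemble confidence bands, founding
    compositions at Hardy-Weinberg-with-selection proportions, a synthetic
    cage-experiment generator, and trajectory analysis of scored
    eye-colour data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
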