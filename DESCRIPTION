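Package: tactqg
Title: Quantitative Genetics of Alternative Reproductive Tactics in
    Two-Generation Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint analysis of intralocus sexual and tactical conflict in
    tactic-structured two-generation pedigrees, motivated by salmonid
    alternative reproductive tactics (females, fighting "hooknose" males,
    and sneaking "jack" males).  Provides validated pedigree input and
    subsetting, Lande-Arnold selection-gradient estimation on standardized
    length at maturity with Poisson analysis-of-deviance significance
    tests, tactic-by-tactic parent-offspring regression heritabilities
    with the Falconer unequal-variance correction and dual null-hypothesis
    tests, tactic descriptives (ANOVA with Tukey HSD, negative-binomial
    reproductive-success models), and a forward simulator of
    tactic-structured pedigrees with a configurable additive-genetic
    architecture and heritable male-tactic liability threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
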