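Package: famgif
Title: Genealogical Index of Familiality Tests for Excess Relatedness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests for excess familial clustering of a phenotype in deep
    genealogies. Implements Malecot kinship and minimum meiotic genetic
    distance on arbitrary pedigrees, the Genealogical Index of Familiality
    (GIF) statistic with matched-control Monte Carlo empirical significance,
    a subset variant that tests whether a clinically defined case subset is
    more related than the case cohort at large, the decomposition of the
    statistic by pairwise genetic distance, and a one-sided Poisson
    observed-versus-expected test for high-risk pedigrees. Includes a
    configurable simulator of multigeneration founder populations with a
    rare dominant variant and clustered phenotypes, a gene-dropping Monte
    Carlo kinship oracle, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
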