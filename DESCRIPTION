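Package: hlaims
Title: Immunogenetic Scoring of HLA Alleles for Melanoma Protection and
    Susceptibility
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Country-level immunogenetic epidemiology of melanoma: scores
    HLA class I and class II alleles as protective or susceptible from the
    Pearson correlation between population allele frequency and melanoma
    prevalence across countries, Fisher z-transformed into an immunogenetic
    melanoma score (IMS). Provides stratified single-proportion inference
    (Wald test, Agresti-Coull intervals) over classes, genes and class I
    supertypes, a Monte Carlo expected score that embeds each allele in
    random 12-allele diploid genotype contexts, an individual genotype risk
    score, a synthetic country-panel generator with planted correlations for
    sign-recovery validation, and bundled allele registry and score tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
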