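Package: polyself
Title: Selfing Genetics and Inbreeding Depression in Diploid and
    Autotetraploid Maize
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Exact single-locus genetics of self-fertilization under
    disomic and tetrasomic inheritance, including double reduction and a
    forced unlike-bivalent pairing model; goodness-of-fit tests of
    karyotype segregation classes against tetrasomic expectations;
    forward Monte Carlo simulation of selfing lineages with optional
    gametophytic selection; a synthetic randomized-complete-block
    field-trial generator with competing trait architectures; and the
    interaction regressions used to compare inbreeding-depression slopes
    between ploidies and genotypes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
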