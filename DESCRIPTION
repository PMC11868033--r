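Package: troutmon
Title: Genetic Monitoring of Introduced Salmonid Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring the genetic consequences of releasing
    fish populations into the wild with diploid biallelic SNP panels.
    Provides genotype readers and writers (GENEPOP, STRUCTURE two-row,
    CSV), within-population diversity and Hardy-Weinberg statistics,
    Weir-Cockerham F-statistics with permutation tests, Nei Da distances
    and bootstrapped neighbor-joining trees, supervised maximum-likelihood
    ancestry estimation against baseline allele frequencies, immigrant
    and introgression calling, linkage-disequilibrium and temporal
    effective population size estimators, the Swedish traffic-light
    indicators for genetic diversity (dH, Ne, dFST), and a forward
    simulator of a two-population release spreading through a lake chain
    with ancestry-linked downstream dispersal and one-way leakage into
    native creek demes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
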