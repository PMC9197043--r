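Package: drivecage
Title: Cage-Trial Dynamics of Self-Eliminating CRISPR Homing Gene Drives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based, discrete-generation simulation of mosquito
    cage trials in which an autonomous, self-eliminating Cas9 driver allele
    mobilises multiple non-autonomous gRNA-only payload drives under
    pre-existing and de novo target-site resistance. Includes the germline
    cut/homology-directed-repair/end-joining gamete model that produces
    super-Mendelian transmission, genotype-specific fertility, single-pair
    cross simulation with transmission and contingency statistics, bootstrap
    estimation of carrier and allele frequencies from genotyped samples,
    classification of amplicon alleles into function-preserving (R1) and
    function-disrupting (R2) cleavage-resistant classes, and synthetic-data
    generators for every input format consumed by the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
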