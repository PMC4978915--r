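Package: sdrmap
Title: Segregation Distortion Analysis for Outbred Diploid Mapping Populations
Version: 0.1.0
Authors@R:
    person("sdrmap", "developers", email = "sdrmap@example.org", role = c("aut", "cre"))
Description: Tools to study segregation distortion in full-sib (CP-type)
    mapping populations of outbred diploids such as potato. Provides
    chi-square goodness-of-fit tests against 1:1 and 1:2:1 Mendelian
    expectations, calling of segregation distortion regions (SDRs) from
    clusters of distorted linked markers, parental haplotype-transmission
    profiling from linkage phases, Marey-map recombination-rate landscapes
    with monotone spline derivatives, and a two-locus linkage-disequilibrium
    (r squared) scan for interactions between unlinked loci. A cross
    simulator with gametic and zygotic selection generates populations with
    known truth so every analysis stage can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
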