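Package: pedilink
Title: Pedigree-Based Carrier Tracing and Linked-Marker Phase Inference for
    Dominant Low-Penetrance Disease
Version: 0.1.0
Authors@R:
    person("Pedilink", "Maintainers", email = "maintainers@pedilink.org",
           role = c("aut", "cre"))
Description: Tools for rule-based genetic appraisal of multi-generation dog
    pedigrees segregating an autosomal dominant disease with very low
    penetrance, modelled on canine arrhythmogenic right ventricular
    cardiomyopathy (ARVC) in Boxers and the linked Striatin (STRN) deletion
    marker. Identifies obligate transmitters from affected progeny with
    several mates, traces lines of descent to founder import sources,
    classifies the remaining population clear-by-pedigree, infers
    coupling/repulsion phase of a linked biallelic marker relative to the
    disease locus, flags meioses where phase switches (recombination
    evidence), computes genotype-association and Hardy-Weinberg chi-square
    statistics, estimates penetrance from segregation ratios, and bundles a
    gene-dropping simulator with full ground-truth logs for validating every
    inference rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
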