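Package: pqtlmr
Title: Proteome-Wide Mendelian Randomization for Drug-Target Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for proteome-wide two-sample Mendelian
    randomization screens of circulating proteins against disease outcomes:
    cis-pQTL instrument selection (genome-wide significance, greedy LD
    clumping, weak-instrument filtering), Wald-ratio and inverse-variance
    weighted causal estimation with Bonferroni control, Steiger and
    bidirectional-MR reverse-causation defenses, Wakefield
    approximate-Bayes-factor colocalization over the five-hypothesis
    enumeration, pleiotropy scanning against a local association catalog,
    same-variant and significant-variant replication, phenome-wide MR
    side-effect screening, and conjunction of all filters into a per-target
    evidence verdict. Includes a seeded generator of LD reference panels and
    paired exposure/outcome GWAS summary statistics with known ground truth,
    so every stage is exercisable end-to-end without restricted consortium
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
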