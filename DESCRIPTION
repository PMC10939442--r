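Package: mtel
Title: Mechanistic and Empirical Translation Error Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models codon-specific amino acid misincorporation during
    translation as a competition between tRNAs for arrival at the ribosome
    combined with effective codon/anticodon binding affinities, and fits the
    affinity parameters to observed misincorporation counts by Markov chain
    Monte Carlo under a multinomial likelihood. Also provides the empirical
    counterpart: calling amino acid substitutions from open-search
    peptide-spectrum-match tables with coverage, localization and
    post-translational-modification filters, dataset curation rules, and
    per-codon error detection rates. A population-genetics layer converts
    incorporation probabilities and variant-effect scores into site and
    protein fitness burdens and Sella-Hirsh relative fixation probabilities,
    with a nearly-neutral classification band. Synthetic generators for tRNA
    pools, misincorporation counts, PSM fixtures and fitness-score tables
    make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    graphics,
    seqinr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
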