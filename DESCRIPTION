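Package: fitcore
Title: Fuzzy Intersection of Transcriptomes for Consensus Drug Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genes consistently regulated by a panel of perturbagens
    from connectivity-map-style ranked expression profiles. Extracts up- and
    down-regulated tail signatures from each profile, counts per-probe support
    across the panel ("fuzzy intersection"), and calibrates the support
    threshold against empirical null models (random-profile resampling or
    within-profile probe permutation) using fold-ratio and empirical p-value
    criteria, with optional gene-set-enrichment refinement of the cut-off.
    Includes downstream hypergeometric overrepresentation, protein-protein
    interaction overlap permutation tests, two-tailed rank-based enrichment
    scoring for drug re-ranking, and a synthetic perturbation-compendium
    generator with planted consensus signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
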