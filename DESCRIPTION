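Package: motifboost
Title: Motif-Centric Isobaric (TMT) Phosphoproteomics with Boosting Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for motif-centric isobaric (TMT) phosphoproteomics,
    in which phosphopeptides generated by in vitro kinase reactions are spiked into
    a boosting channel to raise the detectability of low-stoichiometry kinase
    substrates. Implements the acceptance-criteria filters (boost ratio, intensity
    floor, valid-channel rules), direct-substrate classification from dual TMT
    ratio tests (group A/B logic), channel-ratio phosphorylation-stoichiometry
    estimation, kinase-motif scoring and composition analysis, and a seeded
    synthetic-data generator that simulates the boosting-channel TMT experiment
    (tryptic digestion, back-phosphorylation, MS1 detectability, ion-budget-limited
    reporter sampling) so that every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
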