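Package: crosspath
Title: Risk-Pathway Crosstalk Networks and Drug Combination Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds miRNA-augmented pathway graphs, identifies risk mRNAs and
    miRNAs from tumor/normal expression by differential testing and weighted
    co-expression modules, scores crosstalk between risk pathways by summing
    correlation strengths over interacting cross-pathway feature pairs, and
    screens single drugs and drug pairs by how much removal of their targets
    destroys the crosstalk network. Includes a synthetic-cohort generator with
    planted ground truth (differential features, co-expression modules, risk
    pathways, superadditive drug pairs, survival effects) so the whole
    pipeline is testable without external data, plus Kaplan-Meier/log-rank
    validation of combination target signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
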