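Package: chronodtl
Title: Dated Duplication-Transfer-Loss Reconciliation and Gene-Event Timing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maximum-parsimony reconciliation of rooted gene trees with
    time-calibrated species chronograms under a duplication, transfer and
    loss (DTL) model in which horizontal transfers are restricted to
    contemporaneous lineages. Inferred gene events are assigned time
    ranges from the dated branches on which they occur, summarised by
    midpoint dates, per-gene earliest events, per-gene event-count
    tables and binned temporal trends. Includes a gene-family simulator
    (pure-birth chronograms plus Gillespie duplication/transfer/loss
    histories with a complete dated truth log), an independent
    brute-force reconciliation oracle for validation, and RecPhyloXML
    export of reconciled histories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
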