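Package: echoNER
Title: Weakly Supervised Extraction of Cardiogenic-Stroke Evidence from
    Chinese Echocardiograph Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A character-level named-entity-recognition pipeline for
    identifying diagnosis evidence of cardiogenic stroke in free-text
    Chinese echocardiograph reports.  A clinician-seeded phrase lexicon is
    expanded by regular-expression harvesting, reports are normalized into
    single annotation-ready paragraphs, and a forward-maximum-matching
    pass against the lexicon produces weak BIO supervision.  A
    character-embedding BiLSTM-CRF tagger is trained on the weak labels
    and evaluated under strict span-quadruple matching (report, start,
    end, type), including discovery of novel evidence surface forms absent
    from the lexicon.  Because hospital corpora of this kind cannot be
    redistributed, the package ships a synthetic report generator that
    emulates the documented corpus structure with known gold spans, so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stringi,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
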