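Package: onsettree
Title: Decision-Tree Subtyping of Parkinson's Disease by Age of Onset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline that learns interpretable Parkinson's disease
    subtypes from clinical rating-scale data. A from-scratch CART classifier
    (Gini criterion) is trained to separate early from late onset patients;
    each leaf of the fitted tree is read off as a conjunction-of-conditions
    candidate subtype, which is then filtered through three criteria (minimum
    unique-patient size, sufficient external matches, precision above the
    external class prior) against an independent validation cohort and finally
    characterized (check-sheet ratios, distinguishable features, Rand index
    against external clusterings). A synthetic-cohort generator with planted
    rule-defined subtypes stands in for the access-controlled study data so
    every stage is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    dplyr,
    pROC,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
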