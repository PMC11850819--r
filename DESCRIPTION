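Package: milscreen
Title: Multi-Instance Learning for Depression Screening from Clinical
    Interview Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens for depression from timestamped clinical interview
    transcripts with a multi-instance learning (MIL) framework. Each
    participant's merged question-answer responses form a bag of instances;
    a pluggable per-instance scorer assigns depression confidence scores in
    [0, 1]; bags are labeled by an improved decision rule with a
    high-confidence threshold (alpha) and a depressive-instance count
    threshold (beta). Includes score-averaging ensembles, Monte-Carlo repeat
    uncertainty, perturbation-based local surrogate explanations of
    individual instances, ROC/AUC and threshold-sweep evaluation machinery,
    and a synthetic interview generator so the full pipeline is testable
    without access-restricted corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    graphics,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
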