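Package: rednotes
Title: Redundancy-Aware Topic Modeling for Clustered Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Topic modeling for document collections organised into clusters
    (such as patient records) in which later documents copy and paste text
    from an earlier source document. Implements Red-LDA, a collapsed Gibbs
    sampler for latent Dirichlet allocation in which tokens flagged as copied
    draw their topic from the source note's current assignments of the same
    word and are excluded from the topic-word count statistics; together with
    fingerprint-based detection of copied spans, the DeleteDoc and DeleteWord
    redundancy-elimination baselines, evaluation by held-out log-likelihood
    and co-document-frequency topic coherence, Jensen-Shannon topic
    alignment, and a generator of synthetic clustered corpora with known
    ground truth for parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
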