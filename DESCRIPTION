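Package: ldlfreq
Title: Frequency-Informed Linear Discriminative Learning of the Mental Lexicon
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linear discriminative learning of mappings between
    word forms and distributional semantic vectors. Word forms are coded as
    binary n-gram cue vectors (including a Mandarin-style union of segmental,
    tonal and tone-segment cues) and meanings as real-valued embeddings.
    Mappings can be estimated three ways: endstate learning (ordinary
    multivariate least squares), incremental Widrow-Hoff learning over token
    streams, and frequency-informed learning, a weighted least-squares
    estimator equivalent to endstate learning on frequency-replicated data.
    Evaluation utilities provide target correlations, accuracy at k,
    token-weighted accuracy, a 1 - r latency proxy and priming measures, and
    a trajectory module analyses ordered incremental learning against the
    order-free weighted solution. A synthetic lexicon generator (Zipfian
    frequencies, planted linear semantics, homophones, drifting token
    streams) makes every component testable without external corpora.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
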