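Package: littopics
Title: Topic Modelling of Literature Corpora by Collapsed Gibbs LDA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A pipeline for scientometric topic modelling of bibliographic
    corpora of article abstracts: ingestion and deduplication of RIS, BibTeX
    and CSV records with dual-reviewer screening agreement (Cohen's kappa);
    abstract cleaning (stop-word, number-word and publisher-term removal,
    Porter suffix-stripping stemming, rare-term filtering) into a sparse
    document-term matrix; a collapsed Gibbs sampler for Latent Dirichlet
    Allocation with held-out document-completion perplexity and block
    cross-validated selection of the number of topics; derived statistics
    (decadal topic prevalence, topic co-occurrence, generality versus
    specificity, journal contribution); a Poisson generalised linear mixed
    model of per-topic yearly article counts with random intercepts and
    slopes (topic popularity and trend); country-mention extraction from
    abstracts; and a synthetic-corpus generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    lme4,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
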