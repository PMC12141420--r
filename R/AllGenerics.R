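#' @rdname DocTermMatrix-class
#' @param object,x a \code{DocTermMatrix}.
#' @export
setGeneric("dtmCounts", function(x) standardGeneric("dtmCounts"))

#' @rdname DocTermMatrix-class
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' @rdname DocTermMatrix-class
#' @export
setGeneric("docIds", function(x) standardGeneric("docIds"))

#' @rdname DocTermMatrix-class
#' @export
setGeneric("docFrequency", function(x) standardGeneric("docFrequency"))

#' @rdname DocTermMatrix-class
#' @export
setGeneric("emptyDocs", function(x) standardGeneric("emptyDocs"))

#' @rdname LDAModel-class
#' @export
setGeneric("topicWordDist", function(x) standardGeneric("topicWordDist"))

#' @rdname LDAModel-class
#' @export
setGeneric("docTopicDist", function(x) standardGeneric("docTopicDist"))

#' @rdname LDAModel-class
#' @export
setGeneric("logLikTrace", function(x) standardGeneric("logLikTrace"))

#' Per-topic top words
#'
#' Ranks each topic's terms by word weight (the phi entry) in decreasing
#' order, ties broken lexicographically.  Twenty words per topic is the
#' conventional summary length: weights typically begin to flatten out by
#' then, and the top handful carries most of the interpretable signal.
#'
#' @param x a fitted \code{LDAModel}.
#' @param n number of words per topic (default 20); capped at the
#'   vocabulary size.
#' @return a list (one element per topic) of data.frames with columns
#'   \code{term} and \code{weight}, weights non-increasing.
#' @export
setGeneric("topWords", function(x, n = 20L) standardGeneric("topWords"))

#' @rdname SyntheticCorpus-class
#' @export
setGeneric("truePhi", function(x) standardGeneric("truePhi"))

#' @rdname SyntheticCorpus-class
#' @export
setGeneric("trueTheta", function(x) standardGeneric("trueTheta"))

#' @rdname SyntheticCorpus-class
#' @export
setGeneric("corpusRecords", function(x) standardGeneric("corpusRecords"))

setMethod("dtmCounts", "DocTermMatrix", function(x) x@counts)
setMethod("vocabulary", "DocTermMatrix", function(x) x@terms)
setMethod("docIds", "DocTermMatrix", function(x) x@docIds)
setMethod("docFrequency", "DocTermMatrix", function(x) {
  stats::setNames(x@docFrequency, x@terms)
})
setMethod("emptyDocs", "DocTermMatrix", function(x) {
  stats::setNames(x@emptyDocs, x@docIds)
})

setMethod("topicWordDist", "LDAModel", function(x) x@phi)
setMethod("docTopicDist", "LDAModel", function(x) x@theta)
setMethod("logLikTrace", "LDAModel", function(x) x@logLik)

setMethod("truePhi", "SyntheticCorpus", function(x) x@phiTrue)
setMethod("trueTheta", "SyntheticCorpus", function(x) x@thetaTrue)
setMethod("corpusRecords", "SyntheticCorpus", function(x) x@records)

setMethod("show", "DocTermMatrix", function(object) {
  cat(sprintf(
    "DocTermMatrix: %d documents x %d terms (%d tokens)\n",
    nrow(object@counts), ncol(object@counts), sum(object@counts)
  ))
  cat(sprintf(
    "  min document frequency: %d; empty documents: %d\n",
    object@minDocFrequency, sum(object@emptyDocs)
  ))
})

setMethod("show", "LDAModel", function(object) {
  cat(sprintf(
    "LDAModel: K = %d topics over %d terms, %d documents\n",
    object@K, length(object@terms), length(object@docIds)
  ))
  cat(sprintf(
    "  alpha = %.4g, beta = %.4g, %d sweeps (burn-in %d), seed %d\n",
    object@alpha, object@beta, object@nIter, object@burnIn, object@seed
  ))
  cat(sprintf(
    "  final collapsed log-likelihood: %.2f%s\n",
    object@logLik[length(object@logLik)],
    if (object@averaged) " (phi/theta averaged post burn-in)" else ""
  ))
})

setMethod("show", "LDACV", function(object) {
  cat(sprintf(
    "LDACV: %d-fold block cross-validation over K in {%s}\n",
    object@folds, paste(object@kGrid, collapse = ", ")
  ))
  tab <- data.frame(K = object@kGrid,
                    meanPerplexity = round(object@meanPerplexity, 2))
  print(tab, row.names = FALSE)
  cat(sprintf("  elbow (tol %.3g): K = %d; argmin: K = %d\n",
              object@tol, object@chosenK, object@argminK))
})

setMethod("show", "PopularityFit", function(object) {
  cat(sprintf(
    "PopularityFit: Poisson GLMM, %d topics\n", nrow(object@ranef)
  ))
  cat(sprintf(
    "  fixed: mu = %.3f, gamma = %.3f (year scaled: center %.1f, scale %.3g)\n",
    object@mu, object@gamma, object@yearCenter, object@yearScale
  ))
  cat(sprintf(
    "  random effects: sigma0^2 = %.4f, sigma1^2 = %.4f, rho = %.3f%s\n",
    object@sigma0sq, object@sigma1sq, object@rho,
    if (object@converged) "" else "  [NOT CONVERGED]"
  ))
})

setMethod("show", "SyntheticCorpus", function(object) {
  cat(sprintf(
    "SyntheticCorpus: %d documents, %d true topics, V = %d, years %d-%d\n",
    nrow(object@records), nrow(object@phiTrue), length(object@vocabulary),
    min(object@years), max(object@years)
  ))
  cat(sprintf("  seed %d; injected decoy tokens: %d\n",
              object@seed, nrow(object@noiseLog)))
})
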