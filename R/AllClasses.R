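#' @import methods
#' @importFrom Matrix Matrix t rowSums colSums
#' @importClassesFrom Matrix Matrix CsparseMatrix dgCMatrix
NULL

#' Sparse document-term matrix with vocabulary bookkeeping
#'
#' Documents are rows, stemmed terms are columns.  Terms are kept only when
#' their document frequency reaches \code{minDocFrequency}; documents emptied
#' by the rare-term filter are retained as all-zero rows but flagged in
#' \code{emptyDocs} and excluded from model fitting.
#'
#' @slot counts sparse \code{dgCMatrix}, documents x terms, non-negative
#'   integer counts.
#' @slot terms character vector of vocabulary stems, lexicographically sorted
#'   (C locale) so downstream output is deterministic.
#' @slot docIds character record identifiers, one per row.
#' @slot docFrequency integer, number of documents each term occurs in.
#' @slot emptyDocs logical, \code{TRUE} for rows with no surviving tokens.
#' @slot minDocFrequency the document-frequency threshold applied.
#' @export
setClass("DocTermMatrix",
  representation(
    counts = "Matrix",
    terms = "character",
    docIds = "character",
    docFrequency = "integer",
    emptyDocs = "logical",
    minDocFrequency = "integer"
  )
)

setValidity("DocTermMatrix", function(object) {
  msg <- character()
  m <- object@counts
  if (nrow(m) != length(object@docIds))
    msg <- c(msg, "docIds length must equal number of rows")
  if (ncol(m) != length(object@terms))
    msg <- c(msg, "terms length must equal number of columns")
  if (ncol(m) != length(object@docFrequency))
    msg <- c(msg, "docFrequency length must equal number of columns")
  if (nrow(m) != length(object@emptyDocs))
    msg <- c(msg, "emptyDocs length must equal number of rows")
  if (anyDuplicated(object@docIds))
    msg <- c(msg, "docIds must be unique")
  if (anyDuplicated(object@terms))
    msg <- c(msg, "terms must be unique")
  if (length(msg)) msg else TRUE
})

#' Fitted LDA model (collapsed Gibbs)
#'
#' @slot K number of topics.
#' @slot alpha,beta symmetric Dirichlet concentrations (document-topic and
#'   topic-word).
#' @slot phi K x V topic-word distribution; rows sum to one.
#' @slot theta D x K document-topic distribution ("topic weights"); rows sum
#'   to one.
#' @slot z integer vector of per-token topic assignments (1-based), tokens
#'   ordered by canonical document order then term index.
#' @slot nkv,ndk final count matrices consistent with \code{z}.
#' @slot logLik numeric per-sweep collapsed joint log-likelihood trace.
#' @slot terms,docIds dimension names (fitted documents only).
#' @slot nIter,burnIn,seed sampler settings.
#' @slot averaged logical; whether phi/theta are averages over post-burn-in
#'   samples rather than the final count state.
#' @export
setClass("LDAModel",
  representation(
    K = "integer",
    alpha = "numeric",
    beta = "numeric",
    phi = "matrix",
    theta = "matrix",
    z = "integer",
    nkv = "matrix",
    ndk = "matrix",
    logLik = "numeric",
    terms = "character",
    docIds = "character",
    nIter = "integer",
    burnIn = "integer",
    seed = "integer",
    averaged = "logical"
  )
)

setValidity("LDAModel", function(object) {
  msg <- character()
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (object@alpha <= 0 || object@beta <= 0)
    msg <- c(msg, "alpha and beta must be positive")
  if (nrow(object@phi) != object@K)
    msg <- c(msg, "phi must have K rows")
  if (ncol(object@theta) != object@K)
    msg <- c(msg, "theta must have K columns")
  if (length(object@phi) &&
      max(abs(rowSums(object@phi) - 1)) > 1e-10)
    msg <- c(msg, "phi rows must sum to 1 (tol 1e-10)")
  if (length(object@theta) &&
      max(abs(rowSums(object@theta) - 1)) > 1e-10)
    msg <- c(msg, "theta rows must sum to 1 (tol 1e-10)")
  if (length(object@phi) && min(object@phi) <= 0)
    msg <- c(msg, "phi entries must be strictly positive (beta smoothing)")
  if (length(msg)) msg else TRUE
})

#' Cross-validated topic-number selection result
#'
#' @slot kGrid candidate numbers of topics.
#' @slot perplexity folds x length(kGrid) matrix of held-out document
#'   completion perplexities (NA where a cell was invalid).
#' @slot meanPerplexity per-K mean over valid folds.
#' @slot chosenK elbow choice: smallest K beyond which the relative
#'   improvement in mean perplexity drops below \code{tol}.
#' @slot argminK K with minimal mean perplexity.
#' @slot folds number of document-level blocks.
#' @slot tol relative-improvement tolerance used by the elbow rule.
#' @slot seed RNG seed used for the block shuffle and fits.
#' @export
setClass("LDACV",
  representation(
    kGrid = "integer",
    perplexity = "matrix",
    meanPerplexity = "numeric",
    chosenK = "integer",
    argminK = "integer",
    folds = "integer",
    tol = "numeric",
    seed = "integer"
  )
)

setValidity("LDACV", function(object) {
  msg <- character()
  if (!(object@chosenK %in% object@kGrid))
    msg <- c(msg, "chosenK must be in kGrid")
  if (any(object@perplexity <= 0, na.rm = TRUE))
    msg <- c(msg, "perplexities must be positive")
  if (length(msg)) msg else TRUE
})

#' Poisson GLMM fit of per-topic yearly article counts
#'
#' Model: log E[y_kt] = mu + gamma * t + b0_k + b1_k * t, with t the
#' centred/scaled year and (b0_k, b1_k) bivariate normal across topics.
#' A positive random intercept marks a popular topic; a positive random slope
#' marks a topic increasing in popularity.
#'
#' @slot mu,gamma fixed intercept and fixed year slope (on the scaled year).
#' @slot ranef data.frame with columns topic, b0, b1 (conditional modes).
#' @slot sigma0sq,sigma1sq,rho random-effect variances and correlation.
#' @slot converged logical convergence flag.
#' @slot logLik Laplace-approximated marginal log-likelihood.
#' @slot yearCenter,yearScale the centring/scaling applied to calendar year.
#' @slot fit the underlying \code{merMod} object (or NULL).
#' @export
setClass("PopularityFit",
  representation(
    mu = "numeric",
    gamma = "numeric",
    ranef = "data.frame",
    sigma0sq = "numeric",
    sigma1sq = "numeric",
    rho = "numeric",
    converged = "logical",
    logLik = "numeric",
    yearCenter = "numeric",
    yearScale = "numeric",
    fit = "ANY"
  )
)

setValidity("PopularityFit", function(object) {
  msg <- character()
  if (object@sigma0sq < 0 || object@sigma1sq < 0)
    msg <- c(msg, "variances must be non-negative")
  if (!is.na(object@rho) && abs(object@rho) > 1 + 1e-8)
    msg <- c(msg, "|rho| must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Synthetic corpus with generating truth
#'
#' Holds the generated bibliographic records together with everything needed
#' for recovery tests: the true topic-word and document-topic distributions,
#' per-article year/journal/country assignments, the configuration and seed.
#'
#' @slot records data.frame in the standard bibliographic layout
#'   (record_id, title, abstract, year, journal, source_db).
#' @slot phiTrue K_true x V generating topic-word distribution.
#' @slot thetaTrue D x K_true generating document-topic distribution.
#' @slot tokens list of integer token vectors (term indices) per document,
#'   before any decoy injection.
#' @slot vocabulary the pseudo-word vocabulary.
#' @slot years,journals per-document metadata.
#' @slot countries list of injected country names per document.
#' @slot noiseLog data.frame of injected decoy tokens (empty until
#'   \code{injectNoise} is applied).
#' @slot config the \code{SimulationConfig} used.
#' @slot seed the generating seed.
#' @export
setClass("SyntheticCorpus",
  representation(
    records = "data.frame",
    phiTrue = "matrix",
    thetaTrue = "matrix",
    tokens = "list",
    vocabulary = "character",
    years = "integer",
    journals = "character",
    countries = "list",
    noiseLog = "data.frame",
    config = "list",
    seed = "integer"
  )
)

setValidity("SyntheticCorpus", function(object) {
  msg <- character()
  if (length(object@phiTrue) &&
      max(abs(rowSums(object@phiTrue) - 1)) > 1e-8)
    msg <- c(msg, "phiTrue rows must sum to 1")
  if (length(object@thetaTrue) &&
      max(abs(rowSums(object@thetaTrue) - 1)) > 1e-8)
    msg <- c(msg, "thetaTrue rows must sum to 1")
  if (nrow(object@records) != nrow(object@thetaTrue))
    msg <- c(msg, "one thetaTrue row per record required")
  if (length(msg)) msg else TRUE
})
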