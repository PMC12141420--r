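## Collapsed Gibbs LDA: fitting, held-out perplexity, topic-number
## selection by block cross-validation.

## Expand a DocTermMatrix (or plain matrix) into per-token doc/word index
## vectors in canonical order: documents sorted lexicographically by id,
## tokens within a document by term index.  Returns 0-based indices for C++.
expandTokens <- function(counts, ids) {
  ord <- corderIdx(ids)
  m <- as(counts[ord, , drop = FALSE], "TsparseMatrix")
  o <- order(m@i, m@j)
  di <- rep.int(m@i[o], m@x[o])
  wi <- rep.int(m@j[o], m@x[o])
  list(docIdx = di, wordIdx = wi, ids = ids[ord], order = ord)
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Each token's topic is resampled from the collapsed conditional
#' p(z = k | rest) proportional to (n_dk + alpha)(n_kv + beta)/(n_k. + V beta).
#' After the final sweep, phi and theta are posterior-mean estimates from
#' the count state (or averages over post-burn-in samples when
#' \code{average = TRUE}).  A fixed seed gives bit-identical output;
#' documents are processed in lexicographic record-id order with
#' per-document random streams, so the result does not depend on input row
#' order.
#'
#' @param dtm a \code{\linkS4class{DocTermMatrix}}.  Rows flagged as empty
#'   are excluded from fitting.
#' @param K number of topics (>= 2).
#' @param alpha document-topic Dirichlet concentration; default 50/K.
#' @param beta topic-word Dirichlet concentration; default 0.1.
#' @param nIter total Gibbs sweeps (default 2000).
#' @param burnIn sweeps discarded before any averaging (default 1000).
#' @param seed RNG seed (integer).
#' @param average average phi/theta over post-burn-in samples taken every
#'   \code{sampleEvery} sweeps instead of using the final state.
#' @param sampleEvery thinning interval for averaging.
#' @return an \code{\linkS4class{LDAModel}}.  Convergence is not detected
#'   automatically; inspect \code{logLikTrace()}.
#' @export
fitLDA <- function(dtm, K, alpha = 50 / K, beta = 0.1,
                   nIter = 2000L, burnIn = 1000L, seed = 1L,
                   average = FALSE, sampleEvery = 10L) {
  stopifnot(is(dtm, "DocTermMatrix"))
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  stopifnot(alpha > 0, beta > 0, nIter > burnIn, burnIn >= 0)
  keep <- !dtm@emptyDocs
  if (!any(keep)) stop("no non-empty documents to fit")
  counts <- dtm@counts[keep, , drop = FALSE]
  ids <- dtm@docIds[keep]
  V <- ncol(counts)
  if (V < K)
    warning("number of topics (", K, ") exceeds vocabulary size (", V, ")")
  ex <- expandTokens(counts, ids)
  fit <- cpp_lda_fit(ex$docIdx, ex$wordIdx,
                     D = length(ids), V = V, K = K,
                     alpha = alpha, beta = beta,
                     nIter = as.integer(nIter), burnIn = as.integer(burnIn),
                     seed = as.double(seed),
                     average = isTRUE(average),
                     sampleEvery = as.integer(sampleEvery))
  phi <- fit$phi; theta <- fit$theta
  dimnames(phi) <- list(NULL, dtm@terms)
  dimnames(theta) <- list(ex$ids, NULL)
  new("LDAModel",
      K = K, alpha = alpha, beta = beta,
      phi = phi, theta = theta, z = fit$z,
      nkv = fit$nkv, ndk = fit$ndk,
      logLik = as.numeric(fit$loglik),
      terms = dtm@terms, docIds = ex$ids,
      nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      seed = as.integer(seed), averaged = isTRUE(average))
}

#' Collapsed conditional topic probabilities for one token
#'
#' Exposes the sampler's conditional p(z = k | rest) for a token of word
#' type \code{v} in document \code{d}, given count matrices from which the
#' token itself has already been removed.  Used for validating the sampler
#' against exhaustive enumeration of the collapsed posterior.
#'
#' @param ndk D x K document-topic counts (token removed).
#' @param nkv K x V topic-word counts (token removed).
#' @param nk length-K topic totals (token removed).
#' @param d,v 1-based document and word-type index of the token.
#' @param alpha,beta Dirichlet concentrations.
#' @return probability vector over the K topics.
#' @export
ldaConditional <- function(ndk, nkv, nk, d, v, alpha, beta) {
  cpp_lda_conditional(ndk, nkv, as.integer(nk), as.integer(d),
                      as.integer(v), alpha, beta)
}

#' Held-out perplexity by document completion
#'
#' For each held-out document, a seeded permutation of its tokens is split
#' in half: the first half is folded in by short Gibbs runs against the
#' fixed topic-word distribution to estimate the document's topic weights,
#' and the second half is scored under the mixture
#' sum_k theta_dk phi_kv.  Perplexity is exp(-mean per-token log
#' predictive likelihood); lower is better, and a model predicting
#' uniformly over V words scores exactly V.
#'
#' @param model an \code{\linkS4class{LDAModel}}, or a K x V topic-word
#'   matrix with column names (then \code{alpha} is required).
#' @param heldout a \code{DocTermMatrix} of held-out documents.  Tokens of
#'   terms absent from the model vocabulary are excluded with a warning.
#' @param alpha fold-in document-topic concentration; defaults to the
#'   model's alpha.
#' @param foldIter fold-in Gibbs sweeps per document (default 50).
#' @param seed RNG seed for token permutation and fold-in.
#' @return perplexity (positive scalar), with attributes
#'   \code{"nEval"} (tokens scored) and \code{"nExcluded"} (tokens dropped
#'   for lying outside the vocabulary).
#' @export
perplexity <- function(model, heldout, alpha = NULL, foldIter = 50L,
                       seed = 1L) {
  if (is(model, "LDAModel")) {
    phi <- model@phi
    if (is.null(alpha)) alpha <- model@alpha
    terms <- model@terms
  } else {
    phi <- as.matrix(model)
    if (is.null(alpha)) stop("alpha is required when passing a phi matrix")
    terms <- colnames(phi)
    if (is.null(terms)) stop("phi matrix must carry term column names")
  }
  stopifnot(is(heldout, "DocTermMatrix"))
  keep <- !heldout@emptyDocs
  counts <- heldout@counts[keep, , drop = FALSE]
  ids <- heldout@docIds[keep]

  colMap <- match(heldout@terms, terms)
  excluded <- 0L
  if (anyNA(colMap)) {
    excluded <- as.integer(sum(counts[, is.na(colMap), drop = FALSE]))
    warning(excluded, " held-out token(s) outside the model vocabulary; ",
            "excluded")
    counts <- counts[, !is.na(colMap), drop = FALSE]
    colMap <- colMap[!is.na(colMap)]
  }
  ## re-express counts in model column space
  remap <- Matrix::sparseMatrix(i = seq_along(colMap), j = colMap, x = 1,
                                dims = c(length(colMap), length(terms)))
  counts <- counts %*% remap

  ex <- expandTokens(counts, ids)
  res <- cpp_lda_perplexity(ex$docIdx, ex$wordIdx, phi,
                            alpha = alpha, foldIter = as.integer(foldIter),
                            seed = as.double(seed))
  if (res$nEval == 0) stop("no held-out tokens available for evaluation")
  out <- exp(-res$sumLog / res$nEval)
  attr(out, "nEval") <- as.integer(res$nEval)
  attr(out, "nExcluded") <- excluded
  out
}

#' Block cross-validated selection of the number of topics
#'
#' Documents are shuffled with the given seed and split into
#' \code{folds} contiguous blocks.  For each candidate K and each fold the
#' model is fitted on the remaining blocks and scored by document-completion
#' perplexity on the held-out block.  Cells where K is at least the number
#' of training documents (or the training vocabulary size) are invalid and
#' excluded.  Because the choice of K ultimately trades perplexity against
#' interpretability, both the perplexity argmin and a tolerance-based elbow
#' (smallest K beyond which the relative improvement in mean perplexity
#' falls below \code{tol}) are reported; callers must name the rule they
#' use.
#'
#' @param dtm a \code{DocTermMatrix}.
#' @param kGrid candidate topic numbers; default
#'   \code{c(10, 20, 30, 40, 50, 60, 100, 200)}.
#' @param folds number of document blocks (>= 2, default 5).
#' @param alpha per-K document-topic concentration; default 50/K.
#' @param beta topic-word concentration (default 0.1).
#' @param nIter,burnIn Gibbs sweeps per fold fit (defaults 500/250, chosen
#'   for screening many K values; raise for final fits).
#' @param foldIter fold-in sweeps for perplexity.
#' @param tol relative-improvement tolerance of the elbow rule
#'   (default 0.05).
#' @param seed RNG seed driving the block shuffle and every fold fit.
#' @return an \code{\linkS4class{LDACV}}.
#' @export
crossValidateK <- function(dtm, kGrid = c(10L, 20L, 30L, 40L, 50L, 60L,
                                          100L, 200L),
                           folds = 5L, alpha = NULL, beta = 0.1,
                           nIter = 500L, burnIn = 250L, foldIter = 50L,
                           tol = 0.05, seed = 1L) {
  stopifnot(is(dtm, "DocTermMatrix"))
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  kGrid <- sort(unique(as.integer(kGrid)))
  keep <- !dtm@emptyDocs
  counts <- dtm@counts[keep, , drop = FALSE]
  ids <- dtm@docIds[keep]
  D <- length(ids)
  if (D < folds) stop("need at least one document per fold")

  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restoreSeed(old), add = TRUE)
  perm <- sample.int(D)
  block <- cut(seq_len(D), breaks = folds, labels = FALSE)
  foldOf <- integer(D)
  foldOf[perm] <- block

  perp <- matrix(NA_real_, folds, length(kGrid),
                 dimnames = list(NULL, paste0("K", kGrid)))
  for (f in seq_len(folds)) {
    trainIdx <- foldOf != f
    train <- subsetDtm(dtm, ids[trainIdx])
    test <- subsetDtm(dtm, ids[!trainIdx])
    vEff <- sum(Matrix::colSums(train@counts) > 0)
    for (ki in seq_along(kGrid)) {
      K <- kGrid[ki]
      if (K >= sum(trainIdx) || K >= vEff) next  # invalid cell
      fitSeed <- (seed + 7919L * f + 104729L * ki) %% 2147483647L
      model <- fitLDA(train, K = K,
                      alpha = if (is.null(alpha)) 50 / K else alpha,
                      beta = beta, nIter = nIter, burnIn = burnIn,
                      seed = fitSeed)
      perp[f, ki] <- as.numeric(
        perplexity(model, test, foldIter = foldIter, seed = fitSeed))
    }
  }
  meanPerp <- colMeans(perp, na.rm = TRUE)
  meanPerp[is.nan(meanPerp)] <- NA_real_
  valid <- which(!is.na(meanPerp))
  if (!length(valid)) stop("no valid (K, fold) cells; grid infeasible")
  argminK <- kGrid[valid[which.min(meanPerp[valid])]]
  chosenK <- elbowK(kGrid[valid], meanPerp[valid], tol)
  new("LDACV",
      kGrid = kGrid, perplexity = perp,
      meanPerplexity = as.numeric(meanPerp),
      chosenK = as.integer(chosenK), argminK = as.integer(argminK),
      folds = folds, tol = tol, seed = as.integer(seed))
}

## Smallest K such that moving to the next grid point improves mean
## perplexity by less than tol (relative); argmin when improvements stay
## above tol throughout.
elbowK <- function(ks, perp, tol) {
  if (length(ks) == 1L) return(ks)
  for (i in seq_len(length(ks) - 1L)) {
    improve <- (perp[i] - perp[i + 1L]) / perp[i]
    if (improve < tol) return(ks[i])
  }
  ks[which.min(perp)]
}

subsetDtm <- function(dtm, keepIds) {
  idx <- match(keepIds, dtm@docIds)
  counts <- dtm@counts[idx, , drop = FALSE]
  new("DocTermMatrix",
      counts = counts, terms = dtm@terms, docIds = dtm@docIds[idx],
      docFrequency = dtm@docFrequency,
      emptyDocs = dtm@emptyDocs[idx],
      minDocFrequency = dtm@minDocFrequency)
}

#' @rdname topWords
#' @export
setMethod("topWords", "LDAModel", function(x, n = 20L) {
  n <- min(as.integer(n), length(x@terms))
  lapply(seq_len(x@K), function(k) {
    w <- x@phi[k, ]
    o <- order(-w, x@terms, method = "radix")[seq_len(n)]
    data.frame(term = x@terms[o], weight = unname(w[o]),
               stringsAsFactors = FALSE)
  })
})

#' Serialise / restore a fitted LDA model
#'
#' Writes phi and theta as MatrixMarket files, token assignments and the
#' log-likelihood trace as gzip-compressed text, and the hyperparameters as
#' YAML, into \code{dir}.  \code{readLDAModel} restores an identical model.
#'
#' @param model an \code{\linkS4class{LDAModel}}.
#' @param dir output directory (created if needed).
#' @export
writeLDAModel <- function(model, dir) {
  stopifnot(is(model, "LDAModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(Matrix::Matrix(model@phi, sparse = TRUE),
                     "generalMatrix"), file.path(dir, "phi.mtx"))
  Matrix::writeMM(as(Matrix::Matrix(model@theta, sparse = TRUE),
                     "generalMatrix"), file.path(dir, "theta.mtx"))
  writeLines(model@terms, file.path(dir, "terms.txt"))
  writeLines(model@docIds, file.path(dir, "docs.txt"))
  con <- gzfile(file.path(dir, "assignments.txt.gz"), "w")
  writeLines(as.character(model@z), con); close(con)
  con <- gzfile(file.path(dir, "loglik.txt.gz"), "w")
  writeLines(sprintf("%.17g", model@logLik), con); close(con)
  yaml::write_yaml(list(K = model@K, alpha = model@alpha,
                        beta = model@beta, n_iter = model@nIter,
                        burn_in = model@burnIn, seed = model@seed,
                        averaged = model@averaged),
                   file.path(dir, "hyperparameters.yaml"))
  invisible(dir)
}

#' @rdname writeLDAModel
#' @export
readLDAModel <- function(dir) {
  hp <- yaml::read_yaml(file.path(dir, "hyperparameters.yaml"))
  phi <- as.matrix(Matrix::readMM(file.path(dir, "phi.mtx")))
  theta <- as.matrix(Matrix::readMM(file.path(dir, "theta.mtx")))
  terms <- readLines(file.path(dir, "terms.txt"), encoding = "UTF-8")
  ids <- readLines(file.path(dir, "docs.txt"), encoding = "UTF-8")
  colnames(phi) <- terms
  rownames(theta) <- ids
  z <- as.integer(readLines(gzfile(file.path(dir, "assignments.txt.gz"))))
  ll <- as.numeric(readLines(gzfile(file.path(dir, "loglik.txt.gz"))))
  ## count matrices are reconstructible from z given the token expansion;
  ## stored models keep the distributions, assignments and trace
  K <- as.integer(hp$K)
  new("LDAModel", K = K, alpha = hp$alpha, beta = hp$beta,
      phi = phi, theta = theta, z = z,
      nkv = matrix(0L, K, 0), ndk = matrix(0L, 0, K),
      logLik = ll, terms = terms, docIds = ids,
      nIter = as.integer(hp$n_iter), burnIn = as.integer(hp$burn_in),
      seed = as.integer(hp$seed), averaged = isTRUE(hp$averaged))
}
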