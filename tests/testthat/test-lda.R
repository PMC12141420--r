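# Collapsed Gibbs sampler: conditional correctness against exhaustive
# enumeration, determinism, count conservation, and topic recovery on a
# synthetic corpus with known truth.

makeTinyDtm <- function(tokenLists, ids) {
  buildDtm(tokenLists, ids, cleaningConfig(minDocFrequency = 1L))
}

test_that("collapsed conditionals match exhaustive enumeration (2 docs, 3 words, K=2)", {
  # corpus: doc1 = (w1, w2), doc2 = (w2, w3, w3); K = 2
  docOf <- c(1L, 1L, 2L, 2L, 2L)
  wordOf <- c(1L, 2L, 2L, 3L, 3L)
  D <- 2L; V <- 3L; K <- 2L
  alpha <- 0.7; beta <- 0.3
  N <- length(docOf)
  grid <- as.matrix(expand.grid(rep(list(1:K), N)))
  joint <- apply(grid, 1, collapsedJointLogProb, docOfToken = docOf,
                 wordOfToken = wordOf, D = D, V = V, K = K,
                 alpha = alpha, beta = beta)
  for (base in c(1L, 9L, 20L, 32L)) {
    zBase <- grid[base, ]
    for (i in seq_len(N)) {
      # enumeration: p(z_i = k | z_-i, w) from the joint, holding z_-i fixed
      rows <- apply(grid[, -i, drop = FALSE], 1,
                    function(r) all(r == zBase[-i]))
      pj <- exp(joint[rows] - max(joint[rows]))
      kOfRow <- grid[rows, i]
      pEnum <- vapply(1:K, function(k) sum(pj[kOfRow == k]), numeric(1))
      pEnum <- pEnum / sum(pEnum)
      # implementation: counts with token i removed
      ndk <- matrix(0L, D, K); nkv <- matrix(0L, K, V)
      for (j in seq_len(N)[-i]) {
        ndk[docOf[j], zBase[j]] <- ndk[docOf[j], zBase[j]] + 1L
        nkv[zBase[j], wordOf[j]] <- nkv[zBase[j], wordOf[j]] + 1L
      }
      pImpl <- ldaConditional(ndk, nkv, rowSums(nkv), docOf[i], wordOf[i],
                              alpha, beta)
      expect_equal(pImpl, pEnum, tolerance = 1e-12)
    }
  }
})

test_that("single-word corpus concentrates every topic on that word", {
  dtm <- makeTinyDtm(rep(list(rep("w", 4)), 6), sprintf("d%d", 1:6))
  expect_warning(
    m <- fitLDA(dtm, K = 2, nIter = 50, burnIn = 25, seed = 1, beta = 0.01),
    "vocabulary"
  )
  expect_equal(dim(topicWordDist(m)), c(2L, 1L))
  expect_true(all(topicWordDist(m) == 1))
})

test_that("theta approaches uniform as alpha grows (prior dominates)", {
  dtm <- makeTinyDtm(list(c("a", "a", "b"), c("b", "b", "b")),
                     c("d1", "d2"))
  m <- fitLDA(dtm, K = 2, alpha = 1e7, nIter = 60, burnIn = 30, seed = 2)
  expect_true(max(abs(docTopicDist(m) - 0.5)) < 1e-5)
})

test_that("fits are bit-identical under a fixed seed", {
  co <- generateCorpus(simulationConfig(D = 60L, V = 80L,
                                        meanDocLength = 30, seed = 4L))
  dtm <- corpusDtm(co)
  m1 <- fitLDA(dtm, K = 3, nIter = 80, burnIn = 40, seed = 11)
  m2 <- fitLDA(dtm, K = 3, nIter = 80, burnIn = 40, seed = 11)
  expect_identical(m1@z, m2@z)
  expect_identical(topicWordDist(m1), topicWordDist(m2))
  expect_identical(docTopicDist(m1), docTopicDist(m2))
  m3 <- fitLDA(dtm, K = 3, nIter = 80, burnIn = 40, seed = 12)
  expect_false(identical(m1@z, m3@z))
})

test_that("permuting document order permutes theta rows identically", {
  co <- generateCorpus(simulationConfig(D = 40L, V = 60L,
                                        meanDocLength = 25, seed = 6L))
  dtm <- corpusDtm(co)
  set.seed(1)
  shuffled <- littopics:::subsetDtm(dtm, sample(docIds(dtm)))
  m1 <- fitLDA(dtm, K = 3, nIter = 60, burnIn = 30, seed = 5)
  m2 <- fitLDA(shuffled, K = 3, nIter = 60, burnIn = 30, seed = 5)
  expect_identical(docTopicDist(m1), docTopicDist(m2))
  expect_identical(topicWordDist(m1), topicWordDist(m2))
})

test_that("counts are conserved and consistent with assignments", {
  co <- generateCorpus(simulationConfig(D = 50L, V = 60L,
                                        meanDocLength = 30, seed = 9L))
  dtm <- corpusDtm(co)
  m <- fitLDA(dtm, K = 4, nIter = 60, burnIn = 30, seed = 3)
  counts <- dtmCounts(dtm)[m@docIds, , drop = FALSE]
  expect_equal(rowSums(m@ndk), unname(Matrix::rowSums(counts)))
  expect_equal(sum(m@nkv), sum(counts))
  expect_equal(as.vector(table(factor(m@z, levels = 1:4))),
               unname(rowSums(m@nkv)))
  expect_equal(colSums(m@ndk), unname(rowSums(m@nkv)))
})

test_that("log-likelihood trace is finite and non-degenerate", {
  co <- generateCorpus(simulationConfig(D = 50L, V = 60L,
                                        meanDocLength = 30, seed = 10L))
  m <- fitLDA(corpusDtm(co), K = 3, nIter = 80, burnIn = 40, seed = 7)
  tr <- logLikTrace(m)
  expect_length(tr, 80L)
  expect_true(all(is.finite(tr)))
  expect_gt(length(unique(tr)), 1L)
  # burn-in should improve on initialisation
  expect_gt(mean(tail(tr, 10)), tr[1])
})

test_that("phi and theta rows are stochastic and strictly positive", {
  co <- generateCorpus(simulationConfig(D = 40L, V = 50L,
                                        meanDocLength = 25, seed = 12L))
  m <- fitLDA(corpusDtm(co), K = 3, nIter = 50, burnIn = 25, seed = 1)
  expect_true(max(abs(rowSums(topicWordDist(m)) - 1)) < 1e-10)
  expect_true(max(abs(rowSums(docTopicDist(m)) - 1)) < 1e-10)
  expect_gt(min(topicWordDist(m)), 0)
  mAvg <- fitLDA(corpusDtm(co), K = 3, nIter = 50, burnIn = 25, seed = 1,
                 average = TRUE, sampleEvery = 5)
  expect_true(max(abs(rowSums(topicWordDist(mAvg)) - 1)) < 1e-10)
})

test_that("uniform and single-word perplexities hit their analytic values", {
  co <- generateCorpus(simulationConfig(D = 50L, V = 60L,
                                        meanDocLength = 30, seed = 2L))
  dtm <- corpusDtm(co)
  V <- length(vocabulary(dtm))
  phiU <- matrix(1 / V, 2, V, dimnames = list(NULL, vocabulary(dtm)))
  expect_equal(as.numeric(perplexity(phiU, dtm, alpha = 1)), V,
               tolerance = 1e-10)
  oneWord <- makeTinyDtm(rep(list(rep("w", 6)), 8), sprintf("d%d", 1:8))
  phi1 <- matrix(1, 2, 1, dimnames = list(NULL, "w"))
  expect_equal(as.numeric(perplexity(phi1, oneWord, alpha = 1)), 1,
               tolerance = 1e-12)
})

test_that("perplexity equals a straight-line recomputation on a tiny corpus", {
  # single-word-type documents make the evaluation half analytic: the
  # fold-in theta cancels when all phi rows are identical
  toks <- list(rep("w1", 7), rep("w2", 4), rep("w3", 5), rep("w6", 3))
  dtm <- makeTinyDtm(toks, sprintf("d%d", 1:4))
  pv <- c(w1 = 0.05, w2 = 0.4, w3 = 0.25, w4 = 0.1, w5 = 0.15, w6 = 0.05)
  pv <- pv[vocabulary(dtm)]
  phi <- rbind(pv, pv)
  colnames(phi) <- vocabulary(dtm)
  got <- as.numeric(perplexity(phi, dtm, alpha = 0.5, seed = 3))
  nEval <- sapply(toks, function(t) length(t) - ceiling(length(t) / 2))
  word1 <- sapply(toks, `[`, 1)
  oracle <- exp(-sum(nEval * log(pv[word1])) / sum(nEval))
  expect_equal(got, unname(oracle), tolerance = 1e-10)
})

test_that("out-of-vocabulary held-out tokens are excluded with a warning", {
  co <- generateCorpus(simulationConfig(D = 40L, V = 40L,
                                        meanDocLength = 20, seed = 3L))
  dtm <- corpusDtm(co)
  m <- fitLDA(dtm, K = 2, nIter = 40, burnIn = 20, seed = 1)
  held <- makeTinyDtm(list(c(vocabulary(dtm)[1:4], "neverseen"),
                           vocabulary(dtm)[2:6]),
                      c("h1", "h2"))
  expect_warning(p <- perplexity(m, held), "outside the model vocabulary")
  expect_equal(attr(p, "nExcluded"), 1L)
  expect_gt(as.numeric(p), 0)
})

test_that("topic recovery on a synthetic corpus after matching", {
  co <- generateCorpus(simulationConfig(D = 150L, V = 120L,
                                        meanDocLength = 60, seed = 21L))
  dtm <- corpusDtm(co)
  m <- fitLDA(dtm, K = 5, alpha = 0.1, beta = 0.01,
              nIter = 400, burnIn = 200, seed = 2)
  common <- intersect(vocabulary(dtm), colnames(truePhi(co)))
  mt <- matchTopics(topicWordDist(m)[, common], truePhi(co)[, common])
  expect_gte(mt$meanCosine, 0.9)
  expect_equal(sort(mt$assignment), 1:5)
})

test_that("top words are ranked by weight with lexicographic ties", {
  co <- generateCorpus(simulationConfig(D = 40L, V = 50L,
                                        meanDocLength = 25, seed = 13L))
  m <- fitLDA(corpusDtm(co), K = 3, nIter = 40, burnIn = 20, seed = 1)
  tw <- topWords(m, n = 10)
  expect_length(tw, 3L)
  for (t in tw) {
    expect_equal(nrow(t), 10L)
    expect_true(all(diff(t$weight) <= 0))
  }
  # n beyond V returns the whole vocabulary
  twAll <- topWords(m, n = 10000)
  expect_equal(nrow(twAll[[1]]), length(vocabulary(corpusDtm(co))))
  # single-word corpus: that word everywhere
  one <- makeTinyDtm(rep(list(rep("w", 3)), 6), sprintf("d%d", 1:6))
  expect_warning(
    mOne <- fitLDA(one, K = 2, nIter = 30, burnIn = 10, seed = 1),
    "vocabulary"
  )
  expect_equal(topWords(mOne, 1)[[1]]$term, "w")
})

test_that("cross-validation contracts: default grid, fold guard, ordering", {
  expect_equal(eval(formals(crossValidateK)$kGrid),
               c(10L, 20L, 30L, 40L, 50L, 60L, 100L, 200L))
  co <- generateCorpus(simulationConfig(D = 100L, V = 80L,
                                        meanDocLength = 40, seed = 31L))
  dtm <- corpusDtm(co)
  expect_error(crossValidateK(dtm, kGrid = c(2, 5), folds = 1),
               "folds must be >= 2")
  cv <- crossValidateK(dtm, kGrid = c(2L, 5L), folds = 3,
                       nIter = 200, burnIn = 100, seed = 5)
  expect_s4_class(cv, "LDACV")
  expect_true(all(cv@perplexity > 0, na.rm = TRUE))
  expect_lt(cv@meanPerplexity[2], cv@meanPerplexity[1])
  expect_true(cv@chosenK %in% cv@kGrid)
  # infeasible K cells are invalidated, not fatal
  cv2 <- crossValidateK(dtm, kGrid = c(2L, 5000L), folds = 3,
                        nIter = 100, burnIn = 50, seed = 5)
  expect_true(all(is.na(cv2@perplexity[, "K5000"])))
  expect_equal(cv2@argminK, 2L)
})

test_that("a fitted model round-trips through its serialised form", {
  co <- generateCorpus(simulationConfig(D = 30L, V = 40L,
                                        meanDocLength = 20, seed = 14L))
  m <- fitLDA(corpusDtm(co), K = 3, nIter = 40, burnIn = 20, seed = 2)
  dir <- tempfile()
  writeLDAModel(m, dir)
  back <- readLDAModel(dir)
  expect_equal(topicWordDist(back), topicWordDist(m), tolerance = 1e-12)
  expect_equal(docTopicDist(back), docTopicDist(m), tolerance = 1e-12)
  expect_identical(back@z, m@z)
  expect_equal(logLikTrace(back), logLikTrace(m), tolerance = 1e-15)
  expect_identical(back@K, m@K)
  expect_identical(back@seed, m@seed)
})
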