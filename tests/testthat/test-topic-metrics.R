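test_that("decadal prevalence sums weights within decades and excludes outside years", {
  theta <- rbind(c(0.7, 0.3))
  out <- decadalPrevalence(theta, years = 1995L)
  expect_equal(unname(out$weights[, "1990s"]), c(0.7, 0.3))
  expect_equal(unname(out$weights[, "2000s"]), c(0, 0))

  theta2 <- toyTheta(6, 3)
  yrs <- c(1989L, 1995L, 2003L, 2004L, 2011L, 2019L)
  expect_message(out2 <- decadalPrevalence(theta2, yrs), "excluded")
  expect_equal(attr(out2, "nExcluded"), 1L)  # the 1989 article
  expect_equal(unname(out2$articles), c(1L, 2L, 2L))
  # column sums equal per-decade article counts (theta rows sum to 1)
  expect_equal(unname(colSums(out2$weights)), c(1, 2, 2), tolerance = 1e-12)
  # conservation: decade totals equal totals over the retained years
  expect_equal(sum(out2$weights), 5, tolerance = 1e-12)
})

test_that("prevalence rank table ranks topics within each decade", {
  theta <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3))
  out <- decadalPrevalence(theta, years = c(1995L, 2005L))
  expect_equal(unname(out$ranks[, "1990s"]), c(1L, 2L, 3L))
  expect_equal(unname(out$ranks[, "2000s"]), c(3L, 1L, 2L))
})

test_that("co-occurrence matches a brute-force recomputation", {
  theta <- toyTheta(4, 3, seed = 7)
  out <- topicCooccurrence(theta)
  lt <- log10(theta)
  K <- ncol(theta)
  dBrute <- matrix(0, K, K)
  for (i in 1:K) for (j in 1:K)
    dBrute[i, j] <- sqrt(sum((lt[, i] - lt[, j])^2))
  dmax <- max(dBrute)
  cBrute <- 1 - dBrute / dmax
  diag(cBrute) <- 1
  expect_equal(unname(out$cooccurrence), cBrute, tolerance = 1e-12)
  expect_equal(unname(out$distance), dBrute, tolerance = 1e-12)
})

test_that("co-occurrence endpoints and invariances hold", {
  theta <- toyTheta(5, 3, seed = 9)
  theta[, 2] <- theta[, 1]  # identical weight profiles
  theta <- theta / rowSums(theta)
  out <- topicCooccurrence(theta)
  expect_equal(out$cooccurrence[1, 2], 1, tolerance = 1e-12)
  # the pair attaining dmax maps to 0
  expect_equal(min(out$cooccurrence), 0, tolerance = 1e-12)
  # symmetry, unit diagonal, range
  expect_equal(out$cooccurrence, t(out$cooccurrence))
  expect_equal(unname(diag(out$cooccurrence)), rep(1, 3))
  expect_true(all(out$cooccurrence >= 0 & out$cooccurrence <= 1))
  # permutation of documents leaves the matrix unchanged
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(topicCooccurrence(theta[perm, ])$cooccurrence,
               out$cooccurrence, tolerance = 1e-12)
  # zero weights are rejected with advice
  thetaZero <- theta; thetaZero[1, 1] <- 0
  expect_error(topicCooccurrence(thetaZero), "smoothed")
})

test_that("generality separates selected from unselected weight", {
  # each article loads 0.9 on one distinct topic
  theta <- matrix(0.05, 3, 3); diag(theta) <- 0.9
  g <- topicGenerality(theta)
  expect_equal(g$mean_weight_selected, rep(0.9, 3))
  expect_equal(g$mean_weight_unselected, rep(0.05, 3))
  expect_equal(g$n_selected, rep(1L, 3))

  # uniform theta: every article ties; policy selects topic 1
  thetaU <- matrix(1 / 3, 4, 3)
  expect_message(gU <- topicGenerality(thetaU), "tied")
  expect_equal(gU$n_selected, c(4L, 0L, 0L))
  expect_true(all(is.na(gU$mean_weight_selected[2:3])))
})

test_that("generality matches brute-force enumeration and its conservation law", {
  theta <- toyTheta(5, 3, seed = 31)
  g <- topicGenerality(theta)
  sel <- apply(theta, 1, which.max)
  for (k in 1:3) {
    expect_equal(g$n_selected[k], sum(sel == k))
    if (any(sel == k))
      expect_equal(g$mean_weight_selected[k], mean(theta[sel == k, k]),
                   tolerance = 1e-12)
    expect_equal(g$mean_weight_unselected[k], mean(theta[sel != k, k]),
                 tolerance = 1e-12)
  }
  D <- nrow(theta)
  tot <- sum(ifelse(g$n_selected > 0,
                    g$n_selected * g$mean_weight_selected, 0) +
             (D - g$n_selected) * g$mean_weight_unselected)
  expect_equal(tot, D, tolerance = 1e-12)
})

test_that("article-topic frequency emits both argmax counts and histograms", {
  theta <- matrix(0.05, 6, 3); theta[, 2] <- 0.9
  theta <- theta / rowSums(theta)
  f <- articleTopicFrequency(theta)
  expect_equal(unname(f$argmaxCounts), c(0L, 6L, 0L))
  expect_equal(sum(f$argmaxCounts), 6L)
  expect_equal(unname(rowSums(f$weightHistogram)), rep(6, 3))

  thetaR <- toyTheta(10, 4, seed = 3)
  fR <- articleTopicFrequency(thetaR)
  expect_equal(sum(fR$argmaxCounts), 10L)
  expect_equal(unname(rowSums(fR$weightHistogram)), rep(10, 4))
})

test_that("journal contribution shares match hand computation", {
  recs <- makeRecords(c("a", "b", "c", "d"),
                      journals = c("J1", "J1", "J1", "J2"))
  theta <- toyTheta(4, 2, seed = 5)
  rownames(theta) <- recs$record_id
  jc <- journalContribution(recs, theta)
  expect_equal(jc$counts$journal, c("J1", "J2"))
  expect_equal(jc$counts$share, c(75, 25))
  expect_equal(jc$topShare(1), 75)
  expect_equal(jc$topShare(2), 100)
  # all articles in one journal
  recs1 <- makeRecords(c("a", "b"), journals = c("Only", "Only"))
  jc1 <- journalContribution(recs1, toyTheta(2, 2))
  expect_equal(jc1$topShare(1), 100)
})

test_that("top-N journal share is non-decreasing and profiles are coherent", {
  set.seed(12)
  recs <- makeRecords(sprintf("r%02d", 1:30),
                      journals = sample(paste("J", 1:7), 30, replace = TRUE))
  theta <- toyTheta(30, 4, seed = 8)
  jc <- journalContribution(recs, theta)
  shares <- vapply(1:7, jc$topShare, numeric(1))
  expect_true(all(diff(shares) >= 0))
  expect_equal(shares[7], 100)
  expect_equal(sum(jc$argmaxCounts), 30L)
  expect_equal(unname(rowSums(jc$meanTheta)), rep(1, nrow(jc$counts)),
               tolerance = 1e-12)
})

test_that("metric tables serialise deterministically", {
  theta <- toyTheta(6, 3, seed = 2)
  dir1 <- tempfile(); dir2 <- tempfile()
  m <- list(cooccurrence = topicCooccurrence(theta)["cooccurrence"],
            generality = topicGenerality(theta))
  writeMetricTables(m, dir1)
  writeMetricTables(m, dir2)
  f1 <- list.files(dir1, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
})
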