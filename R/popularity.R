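## Topic popularity: Poisson GLMM of per-topic yearly article counts with
## random intercepts (popularity) and random slopes (trend) per topic.

#' Per-topic yearly article counts
#'
#' Assigns each article to its highest-weighted topic (same tie policy as
#' \code{\link{topicGenerality}}: lowest topic index) and tabulates counts
#' over a zero-filled (topic, year) grid covering every year in the window,
#' including years with no articles.
#'
#' @param theta D x K document-topic matrix or an \code{LDAModel}.
#' @param years integer calendar year per document (NA excluded).
#' @param window year range to cover; defaults to the observed range.
#' @param weighted if TRUE, sum theta weights instead of argmax counts
#'   (response is then non-integer; provided for sensitivity analysis, not
#'   for the Poisson fit).
#' @return data.frame with columns topic, year, count;
#'   \code{sum(count)} over topics equals the article count per year.
#' @export
buildTopicYearCounts <- function(theta, years, window = NULL,
                                 weighted = FALSE) {
  theta <- thetaMatrix(theta)
  stopifnot(length(years) == nrow(theta))
  ok <- !is.na(years)
  theta <- theta[ok, , drop = FALSE]
  years <- as.integer(years[ok])
  if (is.null(window)) window <- range(years)
  yearsGrid <- seq(window[1], window[2])
  K <- ncol(theta)
  grid <- expand.grid(topic = seq_len(K), year = yearsGrid,
                      KEEP.OUT.ATTRS = FALSE)
  inWin <- years >= window[1] & years <= window[2]
  theta <- theta[inWin, , drop = FALSE]
  years <- years[inWin]
  if (weighted) {
    cnt <- matrix(0, K, length(yearsGrid))
    for (j in seq_along(yearsGrid)) {
      rows <- years == yearsGrid[j]
      if (any(rows)) cnt[, j] <- colSums(theta[rows, , drop = FALSE])
    }
    grid$count <- as.vector(cnt)
  } else {
    sel <- argmaxTopics(theta)
    tab <- table(factor(sel, levels = seq_len(K)),
                 factor(years, levels = yearsGrid))
    grid$count <- as.vector(as.matrix(tab))
  }
  grid
}

#' Fit the topic-popularity Poisson GLMM
#'
#' Model: log E[y_kt] = mu + gamma t + b0_k + b1_k t, with t the centred
#' and scaled calendar year and (b0_k, b1_k) bivariate normal across
#' topics.  Estimated by Laplace-approximated maximum likelihood
#' (\code{lme4::glmer}, nAGQ = 1), which is deterministic given the data
#' and optimizer settings.  A positive random intercept marks a topic that
#' is more published than average (popular); a positive random slope marks
#' a topic whose yearly article count is rising.
#'
#' @param counts data.frame with columns topic, year, count (from
#'   \code{\link{buildTopicYearCounts}}).
#' @return a \code{\linkS4class{PopularityFit}}.  Non-convergence is
#'   flagged in \code{@converged}, never silent.
#' @export
fitPopularityGLMM <- function(counts) {
  stopifnot(all(c("topic", "year", "count") %in% names(counts)))
  if (length(unique(counts$topic)) < 2L) stop("need at least 2 topics")
  if (length(unique(counts$year)) < 3L) stop("need at least 3 years")
  if (any(counts$count < 0)) stop("counts must be non-negative")
  yc <- mean(unique(counts$year))
  ys <- stats::sd(unique(counts$year))
  if (ys == 0) stop("year has no variance")
  dat <- data.frame(
    topic = factor(counts$topic),
    yearS = (counts$year - yc) / ys,
    count = counts$count
  )
  warns <- character()
  fit <- withCallingHandlers(
    lme4::glmer(count ~ yearS + (1 + yearS | topic),
                data = dat, family = stats::poisson(link = "log"),
                nAGQ = 1L,
                control = lme4::glmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  conv <- length(fit@optinfo$conv$lme4) == 0 &&
    !any(grepl("converge", warns, ignore.case = TRUE))
  re <- lme4::ranef(fit)$topic
  vc <- lme4::VarCorr(fit)$topic
  fe <- lme4::fixef(fit)
  ranefDf <- data.frame(
    topic = as.integer(as.character(rownames(re))),
    b0 = re[, "(Intercept)"],
    b1 = re[, "yearS"],
    stringsAsFactors = FALSE
  )
  ranefDf <- ranefDf[order(ranefDf$topic), , drop = FALSE]
  rownames(ranefDf) <- NULL
  rho <- if (all(diag(vc) > 0)) stats::cov2cor(vc)[1, 2] else NA_real_
  new("PopularityFit",
      mu = unname(fe["(Intercept)"]), gamma = unname(fe["yearS"]),
      ranef = ranefDf,
      sigma0sq = unname(vc[1, 1]), sigma1sq = unname(vc[2, 2]),
      rho = rho,
      converged = conv,
      logLik = as.numeric(stats::logLik(fit)),
      yearCenter = yc, yearScale = ys,
      fit = fit)
}

#' Classify topics by popularity quadrant
#'
#' Crosses the sign of each topic's random intercept (popular vs. niche)
#' with the sign of its random slope (rising vs. declining):
#' \code{hot} (b0 > 0, b1 > 0), \code{declining-popular} (b0 > 0, b1 < 0),
#' \code{rising-niche} (b0 < 0, b1 > 0), \code{cold} (b0 < 0, b1 < 0).
#' Exact zeros are labelled \code{boundary}.
#'
#' @param fit a \code{\linkS4class{PopularityFit}}, or a data.frame with
#'   columns topic, b0, b1.
#' @return data.frame with columns topic, b0, b1, label.
#' @export
classifyTopics <- function(fit) {
  re <- if (is(fit, "PopularityFit")) fit@ranef else fit
  stopifnot(all(c("topic", "b0", "b1") %in% names(re)))
  lab <- ifelse(re$b0 == 0 | re$b1 == 0, "boundary",
         ifelse(re$b0 > 0 & re$b1 > 0, "hot",
         ifelse(re$b0 > 0, "declining-popular",
         ifelse(re$b1 > 0, "rising-niche", "cold"))))
  data.frame(topic = re$topic, b0 = re$b0, b1 = re$b1, label = lab,
             stringsAsFactors = FALSE)
}

#' Independent per-topic Poisson GLMs
#'
#' Fits a separate \code{glm(count ~ yearS, family = poisson)} per topic on
#' the same centred/scaled year, returning each topic's deviation of
#' intercept and slope from the across-topic means.  Serves as the
#' no-pooling reference against which GLMM empirical-Bayes shrinkage can be
#' checked.
#'
#' @param counts data.frame with columns topic, year, count.
#' @return data.frame with columns topic, d0, d1 (per-topic deviations).
#' @export
perTopicGLM <- function(counts) {
  yc <- mean(unique(counts$year))
  ys <- stats::sd(unique(counts$year))
  topics <- sort(unique(counts$topic))
  coefs <- t(vapply(topics, function(k) {
    d <- counts[counts$topic == k, ]
    f <- suppressWarnings(
      stats::glm(count ~ I((year - yc) / ys), data = d,
                 family = stats::poisson()))
    stats::coef(f)
  }, numeric(2)))
  data.frame(topic = topics,
             d0 = coefs[, 1] - mean(coefs[, 1]),
             d1 = coefs[, 2] - mean(coefs[, 2]))
}
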