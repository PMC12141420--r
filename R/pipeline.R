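## End-to-end convenience wrapper: records -> cleaned DTM -> LDA -> derived
## metric tables.  Mostly plumbing around the module functions; exists so
## that an analysis (and its determinism) can be exercised in one call.

#' Run the full topic-modelling pipeline
#'
#' Cleans the abstracts, builds the document-term matrix, fits LDA by
#' collapsed Gibbs sampling and computes the derived statistics: decadal
#' prevalence, co-occurrence, generality, per-topic article frequency,
#' journal contribution, country mentions and (optionally) the
#' topic-popularity GLMM.  Fully deterministic given records, settings and
#' seed.
#'
#' @param records record collection (see \code{\link{readRecords}}).
#' @param K number of topics.
#' @param cleaning a \code{\link{cleaningConfig}}.
#' @param nIter,burnIn,alpha,beta passed to \code{\link{fitLDA}}.
#' @param seed RNG seed.
#' @param decadeStarts passed to \code{\link{decadalPrevalence}}.
#' @param fitPopularity also fit the Poisson GLMM of per-topic yearly
#'   counts.
#' @param outDir if non-NULL, write all tables as TSV into this directory.
#' @return named list of results (dtm, model and the metric outputs).
#' @export
ldaPipeline <- function(records, K, cleaning = cleaningConfig(),
                        nIter = 2000L, burnIn = 1000L,
                        alpha = 50 / K, beta = 0.1, seed = 1L,
                        decadeStarts = c(1990L, 2000L, 2010L),
                        fitPopularity = TRUE, outDir = NULL) {
  records <- validateRecords(records)
  records <- dropMissingAbstracts(records)
  tokens <- lapply(records$abstract, cleanText, config = cleaning)
  dtm <- buildDtm(tokens, records$record_id, cleaning)
  model <- fitLDA(dtm, K = K, alpha = alpha, beta = beta,
                  nIter = nIter, burnIn = burnIn, seed = seed)
  theta <- docTopicDist(model)
  fitted <- match(rownames(theta), records$record_id)
  years <- records$year[fitted]

  res <- list(
    dtm = dtm,
    model = model,
    topWords = topWords(model),
    prevalence = decadalPrevalence(theta, years,
                                   decadeStarts = decadeStarts),
    cooccurrence = topicCooccurrence(theta),
    generality = topicGenerality(theta),
    frequency = articleTopicFrequency(theta),
    journals = journalContribution(records[fitted, , drop = FALSE], theta),
    countries = extractCountries(records[fitted, , drop = FALSE])
  )
  if (fitPopularity) {
    counts <- buildTopicYearCounts(theta, years)
    res$topicYearCounts <- counts
    res$popularity <- fitPopularityGLMM(counts)
    res$classification <- classifyTopics(res$popularity)
  }
  if (!is.null(outDir)) {
    tables <- list(
      prevalence = res$prevalence["weights"],
      prevalence_ranks = res$prevalence["ranks"],
      cooccurrence = res$cooccurrence["cooccurrence"],
      generality = res$generality,
      frequency_argmax = data.frame(
        topic = seq_len(K), n = as.integer(res$frequency$argmaxCounts)),
      journal_counts = res$journals$counts,
      country_counts = res$countries$counts,
      theta = theta,
      phi = topicWordDist(model)
    )
    if (fitPopularity) {
      tables$topic_year_counts <- res$topicYearCounts
      tables$popularity <- res$classification
    }
    writeMetricTables(tables, outDir)
  }
  res
}
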